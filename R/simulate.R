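#' Configuration for a synthetic association study
#'
#' Describes a synthetic mini-exome: many genes of heterogeneous size mixing
#' rare and common variants under Hardy-Weinberg equilibrium, a quantitative
#' trait driven additively by variants of a few causal genes, a configurable
#' number of independent phenotype replicates over fixed genotypes, and
#' optional long-distance cross-gene genotype correlation ("confounders")
#' that turns designated non-risk genes into spurious-association magnets.
#'
#' @param n_individuals number of (unrelated) individuals.
#' @param n_genes number of genes.
#' @param gene_size_range integer `c(min, max)`; variant count per gene is
#'   uniform on this range.
#' @param gene_sizes optional explicit integer vector of variant counts, one
#'   per gene, overriding `gene_size_range` (useful for deliberately
#'   heterogeneous architectures, e.g. small causal genes among large noise
#'   genes).
#' @param fraction_rare probability that a variant is drawn from the rare
#'   MAF range.
#' @param rare_maf_range MAF range of rare variants, a sub-interval of
#'   (0, 0.01].
#' @param common_maf_range MAF range of common variants (above 0.01).
#' @param causal_genes character vector of causal gene ids (must be valid
#'   ids, `"G0001"`-style, within `n_genes`), or an integer count (the first
#'   so-many genes).
#' @param effect_sizes per-allele effect size for each causal gene's
#'   variants; recycled to `length(causal_genes)`. Within a causal gene
#'   every selected variant gets that gene's effect.
#' @param causal_variants which variants of a causal gene carry effects:
#'   `"rare"` (default), `"common"`, or `"all"`.
#' @param heritability fraction of trait variance explained by the causal
#'   genotypes, in \[0, 1); 0 means the trait is pure noise (and is the
#'   default whenever no causal genes are given).
#' @param n_replicates number of independent phenotype replicates.
#' @param confounders data frame with columns `gene_a`, `gene_b`, `rho`:
#'   for each pair, individuals share gene_a's rare-variant genotypes with
#'   gene_b with probability `rho` (a latent copying indicator), inducing
#'   long-distance correlation between the two genes' rare burdens.
#' @param seed integer seed; the whole study is a deterministic function of
#'   the config.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_individuals = 697,
                              n_genes = 300,
                              gene_size_range = c(2, 30),
                              gene_sizes = NULL,
                              fraction_rare = 0.75,
                              rare_maf_range = c(0.001, 0.01),
                              common_maf_range = c(0.05, 0.4),
                              causal_genes = character(),
                              effect_sizes = 1,
                              causal_variants = c("rare", "common", "all"),
                              heritability = 0.4,
                              n_replicates = 25,
                              confounders = NULL,
                              seed = 1L) {
  causal_variants <- match.arg(causal_variants)
  if (missing(heritability) && length(causal_genes) == 0) heritability <- 0
  stopifnot(n_individuals >= 2, n_genes >= 1,
            length(gene_size_range) == 2,
            gene_size_range[1] >= 1,
            gene_size_range[1] <= gene_size_range[2],
            is.null(gene_sizes) ||
              (length(gene_sizes) == n_genes && all(gene_sizes >= 1)),
            fraction_rare >= 0, fraction_rare <= 1,
            heritability >= 0, heritability < 1,
            n_replicates >= 1)
  if (rare_maf_range[1] <= 0 || rare_maf_range[2] > 0.01 ||
      rare_maf_range[1] > rare_maf_range[2]) {
    stop("rare_maf_range must be a non-empty sub-interval of (0, 0.01]",
         call. = FALSE)
  }
  if (common_maf_range[1] <= 0.01 || common_maf_range[2] > 0.5 ||
      common_maf_range[1] > common_maf_range[2]) {
    stop("common_maf_range must be a non-empty sub-interval of (0.01, 0.5]",
         call. = FALSE)
  }
  gene_ids <- gene_id(seq_len(n_genes))
  if (is.numeric(causal_genes)) {
    stopifnot(length(causal_genes) == 1, causal_genes <= n_genes)
    causal_genes <- gene_ids[seq_len(causal_genes)]
  }
  stopifnot(all(causal_genes %in% gene_ids))
  effect_sizes <- rep_len(as.numeric(effect_sizes),
                          max(length(causal_genes), 1))
  stopifnot(all(is.finite(effect_sizes)))
  if (heritability > 0 && length(causal_genes) == 0) {
    stop("nonzero heritability requires at least one causal gene",
         call. = FALSE)
  }
  if (!is.null(confounders)) {
    stopifnot(is.data.frame(confounders),
              all(c("gene_a", "gene_b", "rho") %in% names(confounders)),
              all(confounders$gene_a %in% gene_ids),
              all(confounders$gene_b %in% gene_ids),
              all(confounders$rho >= 0 & confounders$rho <= 1),
              all(confounders$gene_a != confounders$gene_b))
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_genes = as.integer(n_genes),
         gene_size_range = as.integer(gene_size_range),
         gene_sizes = if (!is.null(gene_sizes)) as.integer(gene_sizes),
         fraction_rare = fraction_rare,
         rare_maf_range = rare_maf_range,
         common_maf_range = common_maf_range,
         causal_genes = as.character(causal_genes),
         effect_sizes = effect_sizes,
         causal_variants = causal_variants,
         heritability = heritability,
         n_replicates = as.integer(n_replicates),
         confounders = confounders,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

gene_id <- function(i) sprintf("G%04d", i)

#' Draw genotypes for a synthetic study
#'
#' Each variant gets a target MAF from the configured spectrum (rare with
#' probability `fraction_rare`) and dosages drawn as `Binomial(2, MAF)` per
#' individual (Hardy-Weinberg, no local LD). Every causal gene is guaranteed
#' at least one variant of the class its effects attach to. For each
#' confounder pair a per-individual latent copying indicator with probability
#' `rho` replaces gene_b's rare-variant genotypes with gene_a's (recycling
#' gene_a's rare columns if sizes differ), which correlates the two genes'
#' rare-variant burdens at level roughly `rho` without any shared causal
#' effect.
#'
#' @param cfg a [simulation_config()].
#' @param seed override of `cfg$seed` (used internally by
#'   [simulate_study()] to stage seeds).
#' @return List with elements `genotypes` (a [genotype_matrix()]) and
#'   `gene_map`.
#' @export
simulate_genotypes <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(seed, {
    n <- cfg$n_individuals
    sizes <- cfg$gene_sizes %||%
      sample_int_range(cfg$gene_size_range[1], cfg$gene_size_range[2],
                       cfg$n_genes)
    genes <- gene_id(seq_len(cfg$n_genes))
    n_var <- sum(sizes)
    gene_of <- rep(seq_len(cfg$n_genes), sizes)
    is_rare <- stats::runif(n_var) < cfg$fraction_rare
    # causal genes must carry at least one variant of the effect class
    need <- switch(cfg$causal_variants, rare = TRUE, common = FALSE,
                   all = NA)
    if (!is.na(need)) {
      for (cg in match(cfg$causal_genes, genes)) {
        idx <- which(gene_of == cg)
        if (!any(is_rare[idx] == need)) is_rare[idx[1]] <- need
      }
    }
    maf <- ifelse(
      is_rare,
      stats::runif(n_var, cfg$rare_maf_range[1], cfg$rare_maf_range[2]),
      stats::runif(n_var, cfg$common_maf_range[1], cfg$common_maf_range[2])
    )
    dos <- matrix(stats::rbinom(n * n_var, 2, rep(maf, each = n)), nrow = n)
    variant_ids <- paste0(genes[gene_of], "_v",
                          unlist(lapply(sizes, seq_len), use.names = FALSE))
    colnames(dos) <- variant_ids
    # long-distance confounding: copy gene_a's rare genotypes into gene_b
    if (!is.null(cfg$confounders)) {
      for (r in seq_len(nrow(cfg$confounders))) {
        a <- match(cfg$confounders$gene_a[r], genes)
        b <- match(cfg$confounders$gene_b[r], genes)
        rho <- cfg$confounders$rho[r]
        a_rare <- which(gene_of == a & is_rare)
        b_rare <- which(gene_of == b & is_rare)
        if (length(a_rare) == 0 || length(b_rare) == 0) next
        src <- a_rare[(seq_along(b_rare) - 1) %% length(a_rare) + 1]
        copy <- stats::runif(n) < rho
        dos[copy, b_rare] <- dos[copy, src]
      }
    }
    gmat <- genotype_matrix(dos, sample_ids = paste0("I", seq_len(n)))
    gmap <- as_gene_map(split(variant_ids, genes[gene_of]), gmat)
    gmap <- gmap[genes]  # restore gene order
    class(gmap) <- c("gene_map", "list")
    list(genotypes = gmat, gene_map = gmap,
         target_maf = stats::setNames(maf, variant_ids))
  })
}

#' Draw phenotype replicates over fixed genotypes
#'
#' The trait is additive in the causal dosages:
#' `y = sum_j beta_j * dosage_j + eps`, with `eps` i.i.d. normal scaled so
#' the realized genetic variance fraction equals the configured
#' heritability; each replicate redraws `eps` only (genotypes are fixed, as
#' in a replicated simulation design). With heritability 0 the trait is pure
#' standard-normal noise.
#'
#' @param genotypes a [genotype_matrix()].
#' @param gene_map the companion `gene_map`.
#' @param cfg a [simulation_config()].
#' @param seed seed for the residual draws (default derived from
#'   `cfg$seed`).
#' @return List of `cfg$n_replicates` phenotype tibbles
#'   (`sample_id`, `value`).
#' @export
simulate_phenotypes <- function(genotypes, gene_map, cfg,
                                seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- length(genotypes$sample_ids)
  genetic <- numeric(n)
  if (cfg$heritability > 0 && length(cfg$causal_genes)) {
    beta <- numeric(length(genotypes$variant_ids))
    for (k in seq_along(cfg$causal_genes)) {
      part <- partition_variants(genotypes, gene_map, cfg$causal_genes[k],
                                 maf_threshold = 0.01)
      idx <- switch(cfg$causal_variants,
                    rare = part$rare, common = part$common,
                    all = c(part$rare, part$common))
      beta[idx] <- cfg$effect_sizes[k]
    }
    genetic <- drop(genotypes$dosages %*% beta)
    gvar <- stats::var(genetic)
    if (gvar == 0) {
      stop("causal variants carry no genetic variance (all monomorphic?) ",
           "but heritability > 0", call. = FALSE)
    }
    sigma <- sqrt(gvar * (1 - cfg$heritability) / cfg$heritability)
  } else {
    genetic <- numeric(n)
    sigma <- 1
  }
  withr::with_seed(seed, {
    lapply(seq_len(cfg$n_replicates), function(r) {
      tibble::tibble(sample_id = genotypes$sample_ids,
                     value = genetic + stats::rnorm(n, 0, sigma))
    })
  })
}

#' Simulate a full study
#'
#' Genotypes, gene map, phenotype replicates, and a truth record (causal
#' genes with effects, confounded pairs) in one deterministic object.
#'
#' @param cfg a [simulation_config()].
#' @return A `simulated_study`: list with `genotypes`, `gene_map`,
#'   `phenotypes` (list of tibbles), `truth`, `config`.
#' @export
simulate_study <- function(cfg) {
  geno <- simulate_genotypes(cfg)
  phen <- simulate_phenotypes(geno$genotypes, geno$gene_map, cfg)
  structure(
    list(genotypes = geno$genotypes, gene_map = geno$gene_map,
         phenotypes = phen,
         truth = list(causal_genes = cfg$causal_genes,
                      effect_sizes = cfg$effect_sizes,
                      causal_variants = cfg$causal_variants,
                      heritability = cfg$heritability,
                      confounders = cfg$confounders,
                      target_maf = geno$target_maf),
         config = cfg),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study> ", length(x$genotypes$sample_ids), " individuals, ",
      length(x$gene_map), " genes, ", length(x$phenotypes),
      " phenotype replicate(s), ", length(x$truth$causal_genes),
      " causal gene(s)\n", sep = "")
  invisible(x)
}

#' Desk-scale preset echoing the GAW17 unrelated-individuals design
#'
#' 697 individuals, 300 genes (scaled down from the 3,205-gene mini-exome),
#' 13 causal genes with a spread of effect sizes, 25 phenotype replicates,
#' a mixed rare/common architecture dominated by rare variants, and five
#' confounded non-risk genes. Effect sizes are illustrative — chosen to
#' spread per-gene power over roughly the (0, 0.95) range — not calibrated
#' to the original data, which is access-restricted.
#'
#' @param seed integer seed.
#' @return A [simulation_config()].
#' @export
gaw17_like_preset <- function(seed = 17L) {
  causal <- gene_id(1:13)
  simulation_config(
    n_individuals = 697,
    n_genes = 300,
    gene_size_range = c(2, 30),
    fraction_rare = 0.75,
    rare_maf_range = c(0.001, 0.01),
    common_maf_range = c(0.05, 0.4),
    causal_genes = causal,
    effect_sizes = seq(0.25, 2, length.out = 13),
    causal_variants = "rare",
    heritability = 0.4,
    n_replicates = 25,
    confounders = data.frame(
      gene_a = gene_id(1:5),
      gene_b = gene_id(101:105),
      rho = 0.9
    ),
    seed = seed
  )
}

#' Write a simulated study to disk
#'
#' Genotypes and gene map as TSV, one phenotype TSV per replicate
#' (`phenotype_001.tsv`, ...), and the truth record as YAML.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(study$genotypes, file.path(dir, "genotypes.tsv"))
  write_gene_map(study$gene_map, study$genotypes,
                 file.path(dir, "gene_map.tsv"))
  for (r in seq_along(study$phenotypes)) {
    readr::write_tsv(study$phenotypes[[r]],
                     file.path(dir, sprintf("phenotype_%03d.tsv", r)),
                     progress = FALSE)
  }
  truth <- study$truth
  truth$target_maf <- NULL
  truth$confounders <- if (!is.null(truth$confounders))
    as.list(as.data.frame(truth$confounders))
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
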