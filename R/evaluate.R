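#' Perturb a gene set with noise and dropout
#'
#' Removes `remove_n` members uniformly at random, then adds `add_n` genes
#' drawn uniformly from the universe outside the base set — the construction
#' used to probe enrichment-test stability when a candidate set carries
#' noise genes or misses true signals.
#'
#' @param base character vector, the base gene set.
#' @param add_n number of noise genes to add.
#' @param remove_n number of base genes to drop (`< length(base)`).
#' @param universe all candidate gene ids.
#' @param seed integer seed.
#' @return Character vector, the perturbed set.
#' @export
perturb_gene_set <- function(base, add_n = 0, remove_n = 0, universe,
                             seed = 1L) {
  stopifnot(add_n >= 0, remove_n >= 0, remove_n < length(base))
  pool <- setdiff(universe, base)
  if (add_n > length(pool)) {
    stop("universe too small: need ", add_n, " non-base genes, have ",
         length(pool), call. = FALSE)
  }
  withr::with_seed(seed, {
    kept <- if (remove_n > 0) sample(base, length(base) - remove_n) else base
    added <- if (add_n > 0) sample(pool, add_n) else character()
    c(kept, added)
  })
}

#' Draw random null gene sets
#'
#' `n_sets` sets of sizes uniform on `size_range`, members drawn without
#' replacement from the universe with all risk genes excluded — the
#' irrelevant-gene sets used to estimate the enrichment tests'
#' false-positive rate.
#'
#' @param universe all gene ids.
#' @param exclude risk genes never to include.
#' @param n_sets number of sets (default 200).
#' @param size_range integer `c(lo, hi)` set-size range (default 3 to 64).
#' @param seed integer seed.
#' @return A [gene_set_collection()] named `random_001`, ...
#' @export
make_random_sets <- function(universe, exclude = character(), n_sets = 200,
                             size_range = c(3, 64), seed = 1L) {
  pool <- setdiff(universe, exclude)
  stopifnot(size_range[1] >= 1, size_range[1] <= size_range[2])
  if (size_range[2] > length(pool)) {
    stop("size_range upper bound exceeds the non-risk universe (",
         length(pool), ")", call. = FALSE)
  }
  sets <- withr::with_seed(seed, {
    sizes <- sample_int_range(size_range[1], size_range[2], n_sets)
    lapply(sizes, function(k) sample(pool, k))
  })
  names(sets) <- sprintf("random_%03d", seq_len(n_sets))
  gene_set_collection(sets)
}

#' Empirical rejection rates with Monte-Carlo error
#'
#' Summarizes a table of p-values into rejection rates at level `alpha`:
#' within each group the rate is the mean over replicates of the fraction of
#' p-values strictly below `alpha` (a false-positive rate over null units, a
#' power over truly associated units), with Monte-Carlo standard error
#' `sqrt(rate * (1 - rate) / n)` over the `n` p-values pooled.
#'
#' @param df tibble with at least columns `p` and `replicate`.
#' @param alpha nominal level, default 0.05.
#' @param ... grouping columns (tidy-select), e.g. `gene_test, method,
#'   condition`.
#' @return Tibble with `rate`, `se`, `n`, `n_replicates` per group.
#' @export
estimate_rates <- function(df, alpha = 0.05, ...) {
  stopifnot(all(c("p", "replicate") %in% names(df)))
  df |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      rate = mean(vapply(split(.data$p, .data$replicate),
                         function(pp) mean(pp < alpha), numeric(1))),
      n = dplyr::n(),
      n_replicates = dplyr::n_distinct(.data$replicate),
      se = sqrt(.data$rate * (1 - .data$rate) / .data$n),
      alpha = alpha,
      .groups = "drop"
    )
}

#' Gene-set evaluation design
#'
#' The battery of sets evaluated in an experiment: the base risk set, its
#' noise-added and signal-removed perturbations, an optional reference null
#' set (e.g., genes causal only for an independent second trait), and random
#' irrelevant sets for the false-positive rate.
#'
#' @param base_set character vector of risk genes (may be empty for a
#'   null-only design).
#' @param add_levels noise-gene counts for the added-noise perturbations.
#' @param remove_levels dropout counts (each `< length(base_set)`).
#' @param reference_set optional character vector, a known-null set.
#' @param n_random_sets number of random null sets (default 200).
#' @param random_size_range size range of random sets (default 3 to 64).
#' @param seed seed for random-set and perturbation draws.
#' @return A `gene_set_design` list.
#' @export
gene_set_design <- function(base_set = character(),
                            add_levels = c(5, 10, 15, 20),
                            remove_levels = c(5, 10),
                            reference_set = NULL,
                            n_random_sets = 200,
                            random_size_range = c(3, 64),
                            seed = 1L) {
  if (length(base_set)) {
    remove_levels <- remove_levels[remove_levels < length(base_set)]
  } else {
    add_levels <- integer()
    remove_levels <- integer()
  }
  structure(
    list(base_set = as.character(base_set),
         add_levels = as.integer(add_levels),
         remove_levels = as.integer(remove_levels),
         reference_set = reference_set,
         n_random_sets = as.integer(n_random_sets),
         random_size_range = as.integer(random_size_range),
         seed = as.integer(seed)),
    class = "gene_set_design"
  )
}

# sample() treats a length-1 x as 1:x; guard the degenerate range
sample_int_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n)
  else sample(seq(lo, hi), n, replace = TRUE)
}

# "base" -> 0, "addK" -> +K, "removeK" -> -K
perturbation_level <- function(condition) {
  x <- sub("^remove", "-", sub("^add", "", condition))
  x[condition == "base"] <- "0"
  as.integer(x)
}

design_sets_for_replicate <- function(design, universe, replicate) {
  sets <- list()
  cond <- character()
  if (length(design$base_set)) {
    sets[["risk"]] <- design$base_set
    cond["risk"] <- "base"
    for (a in design$add_levels) {
      nm <- paste0("add", a)
      sets[[nm]] <- perturb_gene_set(design$base_set, add_n = a,
                                     universe = universe,
                                     seed = design$seed + 7L * replicate + a)
      cond[nm] <- nm
    }
    for (r in design$remove_levels) {
      nm <- paste0("remove", r)
      sets[[nm]] <- perturb_gene_set(design$base_set, remove_n = r,
                                     universe = universe,
                                     seed = design$seed + 11L * replicate + r)
      cond[nm] <- nm
    }
  }
  if (!is.null(design$reference_set)) {
    sets[["reference"]] <- design$reference_set
    cond["reference"] <- "reference"
  }
  list(sets = sets, condition = cond)
}

#' Run a full two-step evaluation experiment
#'
#' Reproduces the replicated evaluation design end to end: simulate a study,
#' run the gene-level collapsing tests on every phenotype replicate with a
#' shared permutation plan, run GSEA and VSEA on the designed gene sets and
#' on random null sets, flag spurious genes from the replicate-level gene
#' p-values, re-run the enrichment with spurious genes excluded, and
#' cross-tabulate empirical power and false-positive rates.
#'
#' Set perturbations (noise genes added, risk genes removed) are
#' re-randomized per replicate; the random null sets are drawn once. When
#' spurious exclusion is on, step 1 is recomputed a second time (it is a
#' deterministic function of the seeds) rather than holding every
#' permutation panel in memory.
#'
#' @param cfg a [simulation_config()].
#' @param design a [gene_set_design()]; defaults to the config's causal
#'   genes with the standard perturbation levels.
#' @param tests gene-level tests to run.
#' @param methods enrichment methods, subset of `c("GSEA", "VSEA")`.
#' @param B shared permutation count (default 500).
#' @param alpha nominal level (default 0.05).
#' @param exponent running-sum exponent.
#' @param maf_threshold rare/common boundary.
#' @param exclude_spurious also evaluate with spurious genes excluded?
#' @param spurious_min_hits threshold for [identify_spurious()]; default
#'   derived from the replicate count by [default_min_hits()].
#' @param verbose print progress to stderr.
#' @return A `burden_experiment`: list with `report` (rates tibble),
#'   `power_curve` (power-versus-perturbation table), `set_pvalues` (raw
#'   per-replicate enrichment p-values), `gene_pvalues`, `spurious` (flagged
#'   genes per test), `design`, `config`.
#' @export
run_experiment <- function(cfg, design = NULL,
                           tests = c("CMC-1", "CMC-count", "WeightSum1",
                                     "WeightSum2"),
                           methods = c("GSEA", "VSEA"),
                           B = 500, alpha = 0.05, exponent = 1,
                           maf_threshold = 0.01,
                           exclude_spurious = TRUE,
                           spurious_min_hits = NULL,
                           verbose = FALSE) {
  tests <- match.arg(tests, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(inherits(cfg, "simulation_config"))
  study <- simulate_study(cfg)
  universe <- names(study$gene_map)
  risk <- cfg$causal_genes
  if (is.null(design)) design <- gene_set_design(base_set = risk,
                                                 seed = cfg$seed + 99L)
  random_sets <- if (design$n_random_sets > 0) {
    make_random_sets(universe, exclude = union(risk, design$reference_set),
                     n_sets = design$n_random_sets,
                     size_range = design$random_size_range,
                     seed = design$seed)
  }
  plan <- permutation_plan(cfg$n_individuals, B = B,
                           seed = cfg$seed + 1000L)
  R <- cfg$n_replicates

  run_pass <- function(drop_genes = character()) {
    gene_rows <- list()
    set_rows <- list()
    for (r in seq_len(R)) {
      if (verbose) message("replicate ", r, "/", R,
                           if (length(drop_genes)) " (spurious excluded)")
      s1 <- run_step1(study$genotypes, study$gene_map,
                      study$phenotypes[[r]], plan,
                      tests = tests, maf_threshold = maf_threshold)
      if (length(drop_genes)) s1 <- exclude_genes(s1, drop_genes)
      gene_rows[[r]] <- dplyr::mutate(tidy(s1), replicate = r)
      des <- design_sets_for_replicate(design, universe, r)
      all_sets <- c(des$sets, unclass(random_sets))
      if (length(all_sets) == 0) next
      rows <- lapply(tests, function(tn) {
        suppressWarnings(
          enrich_sets(s1[[tn]], all_sets, methods = methods,
                      exponent = exponent)
        )
      })
      set_rows[[r]] <- dplyr::bind_rows(rows) |>
        dplyr::mutate(
          replicate = r,
          condition = dplyr::if_else(
            grepl("^random_", .data$set), "random",
            dplyr::coalesce(des$condition[.data$set], .data$set)
          )
        )
    }
    list(genes = dplyr::bind_rows(gene_rows),
         sets = dplyr::bind_rows(set_rows))
  }

  pass1 <- run_pass()
  spurious <- list()
  pass2 <- NULL
  if (exclude_spurious && R >= 2) {
    for (tn in tests) {
      tab <- pass1$genes |>
        dplyr::filter(.data$test == tn) |>
        dplyr::arrange(.data$replicate, .data$gene)
      pv <- dplyr::coalesce(tab$p_analytic, tab$p_permutation)
      genes_order <- sort(unique(tab$gene))
      pmat <- matrix(pv, nrow = R, byrow = TRUE,
                     dimnames = list(NULL, genes_order))
      spurious[[tn]] <- identify_spurious(pmat, risk_genes = risk,
                                          alpha = alpha,
                                          min_hits = spurious_min_hits)
    }
    drop_union <- sort(unique(unlist(spurious, use.names = FALSE)))
    if (length(drop_union)) {
      pass2 <- run_pass(drop_genes = drop_union)
    } else {
      pass2 <- pass1
    }
  }

  set_p <- dplyr::bind_rows(
    dplyr::mutate(pass1$sets, spurious_excluded = FALSE),
    if (!is.null(pass2)) dplyr::mutate(pass2$sets, spurious_excluded = TRUE)
  )
  gene_p <- dplyr::bind_rows(
    dplyr::mutate(pass1$genes, spurious_excluded = FALSE),
    if (!is.null(pass2)) dplyr::mutate(pass2$genes, spurious_excluded = TRUE)
  )

  report <- if (nrow(set_p)) {
    set_p |>
      dplyr::mutate(rate_type = dplyr::if_else(
        .data$condition %in% c("random", "reference"), "fpr", "power")) |>
      estimate_rates(alpha = alpha, .data$gene_test, .data$method,
                     .data$condition, .data$spurious_excluded,
                     .data$rate_type)
  } else tibble::tibble()

  power_curve <- if (nrow(report)) {
    report |>
      dplyr::filter(.data$rate_type == "power") |>
      dplyr::mutate(perturbation = perturbation_level(.data$condition)) |>
      dplyr::arrange(.data$gene_test, .data$method,
                     .data$spurious_excluded, .data$perturbation)
  } else tibble::tibble()

  structure(
    list(report = report, power_curve = power_curve,
         set_pvalues = set_p, gene_pvalues = gene_p,
         spurious = spurious, design = design, config = cfg,
         alpha = alpha, B = B),
    class = "burden_experiment"
  )
}

#' @export
print.burden_experiment <- function(x, ...) {
  cat("<burden_experiment> ", x$config$n_replicates, " replicate(s), B=",
      x$B, ", alpha=", x$alpha, "\n", sep = "")
  if (length(x$spurious)) {
    cat("  spurious genes flagged:",
        paste0(names(x$spurious), "=", lengths(x$spurious), collapse = ", "),
        "\n")
  }
  print(x$report, n = 20)
  invisible(x)
}

#' @export
tidy.burden_experiment <- function(x, ...) x$report

#' @export
glance.burden_experiment <- function(x, ...) {
  tibble::tibble(
    n_replicates = x$config$n_replicates,
    n_genes = x$config$n_genes,
    n_individuals = x$config$n_individuals,
    B = x$B, alpha = x$alpha,
    n_spurious = length(unique(unlist(x$spurious)))
  )
}
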