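#' Transform gene p-values into gene scores
#'
#' Gene scores are `-log10(p)`, applied identically to observed and permuted
#' p-values so the two remain comparable. Zero p-values (which the add-one
#' permutation estimator never produces) are clipped to the smallest
#' representable permutation p with a warning.
#'
#' @param p numeric vector or matrix of p-values in (0, 1].
#' @param floor clip value for p = 0; default `1e-300`.
#' @return `-log10(p)`, same shape as `p`.
#' @export
scores_from_pvalues <- function(p, floor = 1e-300) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]",
                                             call. = FALSE)
  if (any(p == 0, na.rm = TRUE)) {
    warning("p-value of 0 clipped to ", floor, call. = FALSE)
    p[p == 0] <- floor
  }
  -log10(p)
}

#' Running-sum enrichment score
#'
#' The weighted Kolmogorov-Smirnov-like statistic of gene set enrichment
#' analysis. Genes are ranked by decreasing score (ties broken by gene-id
#' order, for determinism); walking down the ranked list the running sum
#' gains `|score|^exponent / sum over members of |score|^exponent` at member
#' genes and loses `1 / (n_genes - n_members)` at non-members. The
#' enrichment score ES is the running sum's maximum-magnitude deviation from
#' zero, with its sign. With `exponent = 0` this is the classical KS
#' statistic between member and non-member rank distributions (up to sign).
#'
#' @param scores named numeric vector of gene scores (names = gene ids).
#' @param members character vector of member gene ids; must be a non-empty
#'   proper subset of the score names.
#' @param exponent weighting exponent, default 1 (0 gives the unweighted KS
#'   form). If all member scores are zero the member increments fall back to
#'   equal weights `1 / n_members`.
#' @return ES, a single number in \[-1, 1\].
#' @export
enrichment_score <- function(scores, members, exponent = 1) {
  genes <- names(scores)
  if (is.null(genes)) stop("scores must be named by gene id", call. = FALSE)
  unknown <- setdiff(members, genes)
  if (length(unknown)) {
    stop("gene set member(s) not in score panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- length(members)
  if (m == 0 || m >= length(genes)) {
    stop("gene set must be a non-empty proper subset of the scored genes",
         call. = FALSE)
  }
  ord <- order(-scores, genes)
  hit <- genes[ord] %in% members
  running_sum_es(scores[ord], hit, exponent)
}

# core running sum on an already-ranked score vector
running_sum_es <- function(ranked_scores, hit, exponent) {
  w <- abs(ranked_scores[hit])^exponent
  tot <- sum(w)
  inc <- if (tot > 0) w / tot else rep(1 / sum(hit), sum(hit))
  step <- numeric(length(ranked_scores))
  step[hit] <- inc
  step[!hit] <- -1 / sum(!hit)
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' GSEA permutation test for one gene set
#'
#' Computes the observed enrichment score of the set on the panel's observed
#' gene scores, re-computes it on every phenotype-permutation row of the
#' panel (same set, same formula), and reports the one-sided permutation
#' p-value `p = (1 + #\{b : ES_b >= ES\}) / (B + 1)` — enrichment of
#' association signal, not depletion, is the alternative. With
#' `null = "geneset"` the null instead resamples random gene sets of the same
#' size from the observed scores, the "gene sets drawn at random" form.
#'
#' @param panel a `gene_score_panel` from [run_step1()].
#' @param set character vector of member gene ids (or a single set from a
#'   `gene_set_collection`).
#' @param exponent running-sum weighting exponent, default 1.
#' @param null `"phenotype"` (default; uses the panel's shared permutation
#'   rows) or `"geneset"` (random sets of equal size).
#' @param n_null number of random sets when `null = "geneset"`.
#' @param seed seed for the gene-resampling null.
#' @param set_name label for the output row.
#' @return One-row tibble: `set`, `method`, `gene_test`, `es`, `p`,
#'   `set_size`, `B`.
#' @export
gsea_test <- function(panel, set, exponent = 1,
                      null = c("phenotype", "geneset"),
                      n_null = 1000, seed = 1L, set_name = NA_character_) {
  null <- match.arg(null)
  method <- if (isTRUE(panel$adjusted)) "VSEA" else "GSEA"
  enrich_one(panel, set, exponent, null, n_null, seed, set_name, method)
}

enrich_one <- function(panel, set, exponent, null, n_null, seed,
                       set_name, method) {
  stopifnot(inherits(panel, "gene_score_panel"))
  set <- unique(as.character(set))
  es_obs <- enrichment_score(panel$score_obs, set, exponent)
  if (null == "phenotype") {
    es_null <- es_perm_rows(panel, set, exponent)
    B <- panel$B
  } else {
    genes <- panel$genes
    es_null <- withr::with_seed(seed, vapply(seq_len(n_null), function(i) {
      enrichment_score(panel$score_obs, sample(genes, length(set)), exponent)
    }, numeric(1)))
    B <- n_null
  }
  p <- (1 + sum(es_null >= es_obs)) / (B + 1)
  size <- length(set)
  tibble::tibble(set = set_name, method = method, gene_test = panel$test,
                 es = es_obs, p = p, set_size = size, B = B)
}

es_perm_rows <- function(panel, set, exponent) {
  genes <- panel$genes
  is_member <- genes %in% set
  vapply(seq_len(panel$B), function(b) {
    sc <- panel$score_perm[b, ]
    ord <- order(-sc, genes)
    running_sum_es(sc[ord], is_member[ord], exponent)
  }, numeric(1))
}

#' Standardize a panel's gene scores by their permutation null
#'
#' The VSEA adjustment. Gene-level score null distributions differ across
#' genes — larger genes and genes with more common variants spread more — so
#' raw scores are not comparable across genes. For each gene the mean and
#' standard deviation of its `B` permutation scores are taken as that gene's
#' own null location and scale, and both the observed score and every
#' permutation row are standardized by them. After adjustment every gene's
#' permutation score column has mean 0 and sd 1. Genes whose permutation
#' scores are constant (sd 0) get adjusted scores of 0 and a degeneracy
#' flag. The operation is idempotent.
#'
#' @param panel a `gene_score_panel`.
#' @return The adjusted panel (`adjusted = TRUE`); [gsea_test()] on it labels
#'   results `VSEA`.
#' @export
vsea_adjust <- function(panel) {
  stopifnot(inherits(panel, "gene_score_panel"))
  if (panel$B < 10) {
    stop("refusing to standardize on fewer than 10 permutations (B = ",
         panel$B, "): per-gene null moments would be unstable", call. = FALSE)
  }
  mu <- colMeans(panel$score_perm)
  # denominator B (population form): makes the adjustment exactly idempotent
  sdv <- sqrt(colMeans(sweep(panel$score_perm, 2, mu)^2))
  zero <- sdv == 0
  sdv[zero] <- 1
  panel$score_obs <- (panel$score_obs - mu) / sdv
  panel$score_perm <- sweep(sweep(panel$score_perm, 2, mu), 2, sdv, "/")
  if (any(zero)) {
    panel$score_obs[zero] <- 0
    panel$score_perm[, zero] <- 0
    panel$degenerate[zero] <- TRUE
  }
  panel$adjusted <- TRUE
  panel
}

#' VSEA permutation test for one gene set
#'
#' Identical to [gsea_test()] but computed on the
#' permutation-standardized panel (see [vsea_adjust()]); results are
#' labelled `VSEA`.
#'
#' @inheritParams gsea_test
#' @return One-row tibble as [gsea_test()].
#' @export
vsea_test <- function(panel, set, exponent = 1,
                      null = c("phenotype", "geneset"),
                      n_null = 1000, seed = 1L, set_name = NA_character_) {
  null <- match.arg(null)
  if (!isTRUE(panel$adjusted)) panel <- vsea_adjust(panel)
  enrich_one(panel, set, exponent, null, n_null, seed, set_name, "VSEA")
}

#' Enrichment tests over a whole gene-set collection
#'
#' Runs [gsea_test()] and/or [vsea_test()] for every set in a collection
#' against one gene score panel and binds the rows. Set members absent from
#' the panel are dropped with a warning (they carry no score); sets left
#' empty or covering the whole panel are skipped with a warning.
#'
#' @param panel a `gene_score_panel`.
#' @param sets a `gene_set_collection` or named list of gene id vectors.
#' @param methods any of `"GSEA"`, `"VSEA"`.
#' @param exponent running-sum exponent, default 1.
#' @param null,n_null,seed passed to [gsea_test()].
#' @return Tibble with one row per set x method.
#' @export
enrich_sets <- function(panel, sets, methods = c("GSEA", "VSEA"),
                        exponent = 1, null = c("phenotype", "geneset"),
                        n_null = 1000, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  null <- match.arg(null)
  stopifnot(inherits(panel, "gene_score_panel"))
  panels <- list()
  if ("GSEA" %in% methods) panels$GSEA <- panel
  if ("VSEA" %in% methods) panels$VSEA <- vsea_adjust(panel)
  out <- purrr::imap(sets, function(members, nm) {
    known <- intersect(members, panel$genes)
    if (length(known) < length(members)) {
      warning("set '", nm, "': dropping ", length(members) - length(known),
              " member(s) absent from the panel", call. = FALSE)
    }
    if (length(known) == 0 || length(known) >= length(panel$genes)) {
      warning("set '", nm, "' skipped: not a proper non-empty subset",
              call. = FALSE)
      return(NULL)
    }
    dplyr::bind_rows(lapply(names(panels), function(m) {
      enrich_one(panels[[m]], known, exponent, null, n_null, seed, nm, m)
    }))
  })
  dplyr::bind_rows(out)
}
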