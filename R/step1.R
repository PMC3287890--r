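#' Run gene-level collapsing tests across all genes
#'
#' The step-1 engine. For every gene and every requested test it computes the
#' observed association statistic and the same statistic under every
#' phenotype permutation of a shared [permutation_plan()] — the same
#' reshuffled phenotype is applied to all genes within one permutation, so
#' inter-gene correlation survives into the null and can be exploited by the
#' set-enrichment step. Permutation p-values use the add-one estimator
#' `p = (1 + #\{b : T_b >= T\}) / (B + 1)`, which never returns zero.
#'
#' Tests:
#' \describe{
#'   \item{CMC-1}{carrier indicator over rare variants (MAF <= threshold)
#'     plus each common variant, joint F statistic.}
#'   \item{CMC-count}{rare-allele count plus common variants, joint F.}
#'   \item{WeightSum1}{frequency-weighted sum over all variants, absolute
#'     centered cross product with the trait (permutation-only p).}
#'   \item{WeightSum2}{frequency-weighted sum, simple-regression F
#'     (equivalently squared slope t).}
#' }
#'
#' Genes with no polymorphic variants (or an empty rare set for the CMC
#' collapse when no common variants remain) are flagged degenerate and carry
#' statistic 0 / p-value 1 rather than being dropped, so gene-set membership
#' bookkeeping stays intact downstream.
#'
#' @param g a [genotype_matrix()]; missing dosages are mean-imputed.
#' @param gene_map a `gene_map` (see [as_gene_map()]).
#' @param phenotype phenotype tibble (`sample_id`, `value`) or aligned
#'   numeric vector.
#' @param tests subset of `c("CMC-1", "CMC-count", "WeightSum1",
#'   "WeightSum2")`.
#' @param plan a [permutation_plan()]; its sample count must match `g`.
#' @param maf_threshold rare/common MAF boundary, default 0.01 (inclusive).
#' @return A `step1_result`: named list of `gene_score_panel` objects, one
#'   per test. Use [tidy()] for a per-gene tibble.
#' @export
run_step1 <- function(g, gene_map, phenotype, plan,
                      tests = c("CMC-1", "CMC-count", "WeightSum1",
                                "WeightSum2"),
                      maf_threshold = 0.01) {
  tests <- match.arg(tests, several.ok = TRUE)
  stopifnot(inherits(g, "genotype_matrix"), inherits(plan, "permutation_plan"))
  g <- impute_mean(g)
  y <- align_phenotype(g, phenotype)
  n <- length(y)
  if (plan$n != n) stop("permutation plan built for ", plan$n,
                        " samples, data has ", n, call. = FALSE)
  genes <- names(gene_map)
  G <- length(genes)
  B <- plan$B
  # columns: observed y then each permuted y
  Y <- cbind(y, matrix(y[t(plan$perms)], nrow = n))
  Yc <- Y - mean(y)
  sumYsq <- colSums(Y^2)
  tss <- sum((y - mean(y))^2)
  const_y <- tss == 0

  stat <- lapply(tests, function(t) matrix(0, nrow = B + 1, ncol = G))
  names(stat) <- tests
  # analytic p of observed and every permuted statistic (CMC/WeightSum2);
  # degenerate genes keep p = 1 throughout
  p_score <- lapply(tests, function(t) matrix(1, nrow = B + 1, ncol = G))
  names(p_score) <- tests
  degen <- lapply(tests, function(t) logical(G))
  names(degen) <- tests

  f_stats <- function(X) {
    # F of Y ~ 1 + X vs Y ~ 1 for every column of Y at once
    keep <- apply(X, 2, function(col) stats::sd(col) > 0)
    X <- X[, keep, drop = FALSE]
    if (ncol(X) == 0) return(NULL)
    qrX <- qr(cbind(1, X))
    k <- qrX$rank - 1L
    if (k < 1L) return(NULL)
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    rss <- pmax(sumYsq - colSums(crossprod(Q, Y)^2), 0)
    df2 <- n - qrX$rank
    f <- ((tss - rss) / k) / pmax(rss / df2, .Machine$double.xmin)
    list(f = f, df1 = k, df2 = df2)
  }

  for (gi in seq_len(G)) {
    part <- partition_variants(g, gene_map, genes[gi], maf_threshold)
    poly <- c(part$rare, part$common)
    cmc_tests <- intersect(tests, c("CMC-1", "CMC-count"))
    for (tn in cmc_tests) {
      mode <- if (tn == "CMC-1") "indicator" else "count"
      if (length(poly) == 0 || const_y) { degen[[tn]][gi] <- TRUE; next }
      collapsed <- cmc_collapse(g, part$rare, mode)
      X <- cbind(collapsed$values,
                 if (length(part$common))
                   g$dosages[, part$common, drop = FALSE])
      res <- f_stats(X)
      if (is.null(res)) { degen[[tn]][gi] <- TRUE; next }
      stat[[tn]][, gi] <- res$f
      p_score[[tn]][, gi] <- stats::pf(res$f, res$df1, res$df2,
                                       lower.tail = FALSE)
    }
    ws_tests <- intersect(tests, c("WeightSum1", "WeightSum2"))
    if (length(ws_tests)) {
      if (length(poly) == 0 || const_y) {
        for (tn in ws_tests) degen[[tn]][gi] <- TRUE
      } else {
        s <- weighted_sum_collapse(g, poly)
        sv <- s$values
        if (stats::sd(sv) == 0) {
          for (tn in ws_tests) degen[[tn]][gi] <- TRUE
        } else {
          if ("WeightSum1" %in% tests) {
            stat[["WeightSum1"]][, gi] <- abs(crossprod(Yc, sv - mean(sv)))
          }
          if ("WeightSum2" %in% tests) {
            res <- f_stats(matrix(sv, ncol = 1))
            stat[["WeightSum2"]][, gi] <- res$f
            p_score[["WeightSum2"]][, gi] <-
              stats::pf(res$f, res$df1, res$df2, lower.tail = FALSE)
          }
        }
      }
    }
  }

  panels <- lapply(tests, function(tn) {
    analytic <- tn != "WeightSum1"
    gene_score_panel(
      genes = genes, test = tn,
      stat_obs = stat[[tn]][1, ],
      stat_perm = stat[[tn]][-1, , drop = FALSE],
      p_analytic = if (analytic) p_score[[tn]][1, ]
                   else rep(NA_real_, G),
      degenerate = degen[[tn]],
      seed = plan$seed,
      score_p_obs = if (analytic) p_score[[tn]][1, ],
      score_p_perm = if (analytic) p_score[[tn]][-1, , drop = FALSE]
    )
  })
  names(panels) <- tests
  structure(panels, class = c("step1_result", "list"))
}

#' Construct a gene score panel
#'
#' A `gene_score_panel` carries, for one gene-level test, the observed
#' statistic per gene and the `B x genes` matrix of the same statistic under
#' shared phenotype permutations, plus derived p-values and `-log10(p)` gene
#' scores. Two p-value tracks coexist:
#' \itemize{
#'   \item `p_permutation` / `p_perm_rows` — the rank-among-permutations
#'     transform `(1 + #\{b : T_b >= t\}) / (B + 1)`, applied identically to
#'     the observed statistic and to every permutation row (whose count
#'     includes the row itself). These are the calibrated gene-level
#'     permutation p-values.
#'   \item the score track — gene scores are `-log10` of the p fed through
#'     `score_p_obs` / `score_p_perm` when supplied (the analytic p of the
#'     observed and of each permuted statistic, for tests that have one),
#'     falling back to the rank-based track otherwise. Analytic p-values are
#'     deliberately used raw here: their per-gene miscalibration — driven by
#'     gene size and allele-frequency composition — is exactly what the
#'     downstream permutation standardization ([vsea_adjust()]) measures and
#'     removes, while the running-sum test's own permutation null keeps
#'     either choice valid.
#' }
#'
#' @param genes character gene ids.
#' @param test test name.
#' @param stat_obs numeric vector of observed statistics (one per gene).
#' @param stat_perm numeric `B x genes` matrix of permuted statistics.
#' @param p_analytic analytic p-values where defined, else `NA`.
#' @param degenerate logical per-gene degeneracy flags.
#' @param seed seed recorded from the permutation plan.
#' @param score_p_obs,score_p_perm optional p-values feeding the score
#'   track: a length-`genes` vector and a `B x genes` matrix computed by the
#'   identical procedure on observed and permuted statistics.
#' @return Object of class `gene_score_panel`.
#' @export
gene_score_panel <- function(genes, test, stat_obs, stat_perm,
                             p_analytic = rep(NA_real_, length(genes)),
                             degenerate = rep(FALSE, length(genes)),
                             seed = NA_integer_,
                             score_p_obs = NULL, score_p_perm = NULL) {
  G <- length(genes)
  stopifnot(length(stat_obs) == G, ncol(stat_perm) == G,
            length(p_analytic) == G, length(degenerate) == G,
            is.null(score_p_obs) == is.null(score_p_perm))
  B <- nrow(stat_perm)
  p_obs <- numeric(G)
  p_perm <- matrix(0, B, G)
  for (gi in seq_len(G)) {
    v <- stat_perm[, gi]
    p_obs[gi] <- (1 + sum(v >= stat_obs[gi])) / (B + 1)
    p_perm[, gi] <- (B + 2 - rank(v, ties.method = "min")) / (B + 1)
  }
  if (is.null(score_p_obs)) {
    score_p_obs <- p_obs
    score_p_perm <- p_perm
  }
  stopifnot(length(score_p_obs) == G, all(dim(score_p_perm) == c(B, G)))
  dimnames(stat_perm) <- list(NULL, genes)
  dimnames(p_perm) <- list(NULL, genes)
  dimnames(score_p_perm) <- list(NULL, genes)
  structure(
    list(genes = as.character(genes), test = test, B = as.integer(B),
         seed = seed,
         stat_obs = stats::setNames(stat_obs, genes),
         stat_perm = stat_perm,
         p_analytic = stats::setNames(p_analytic, genes),
         p_permutation = stats::setNames(p_obs, genes),
         p_perm_rows = p_perm,
         score_obs = stats::setNames(scores_from_pvalues(score_p_obs),
                                     genes),
         score_perm = scores_from_pvalues(score_p_perm),
         degenerate = stats::setNames(degenerate, genes),
         adjusted = FALSE),
    class = "gene_score_panel"
  )
}

#' @export
print.gene_score_panel <- function(x, ...) {
  cat("<gene_score_panel> test=", x$test, ", ", length(x$genes),
      " genes, B=", x$B,
      if (isTRUE(x$adjusted)) ", permutation-standardized", "\n", sep = "")
  invisible(x)
}

#' @export
print.step1_result <- function(x, ...) {
  cat("<step1_result> tests:", paste(names(x), collapse = ", "), "\n")
  for (p in x) print(p)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.gene_score_panel <- function(x, ...) {
  tibble::tibble(
    gene = x$genes, test = x$test,
    statistic = unname(x$stat_obs),
    p_analytic = unname(x$p_analytic),
    p_permutation = unname(x$p_permutation),
    score = unname(x$score_obs),
    degenerate = unname(x$degenerate)
  )
}

#' @export
glance.gene_score_panel <- function(x, ...) {
  tibble::tibble(test = x$test, n_genes = length(x$genes), B = x$B,
                 seed = x$seed, adjusted = isTRUE(x$adjusted))
}

#' @export
tidy.step1_result <- function(x, ...) {
  dplyr::bind_rows(lapply(x, tidy))
}

#' @export
glance.step1_result <- function(x, ...) {
  dplyr::bind_rows(lapply(x, glance))
}

#' Write / read a step-1 panel sidecar
#'
#' The sidecar keeps the full permutation statistic matrices (with seed and
#' `B`) so the enrichment step can run later without re-running step 1; the
#' companion TSV from [tidy()] holds only the per-gene summaries.
#'
#' @param x a `step1_result` or `gene_score_panel`.
#' @param path sidecar path (`.rds`).
#' @return `path` (write) or the restored object (read).
#' @export
write_panel <- function(x, path) {
  stopifnot(inherits(x, "step1_result") || inherits(x, "gene_score_panel"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "step1_result") || inherits(x, "gene_score_panel"))
  x
}
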