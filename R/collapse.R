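#' Collapse rare variants into a single burden variable
#'
#' The CMC-style collapse: `mode = "indicator"` scores each individual 1 if
#' they carry at least one minor allele at any of the rare variants (the
#' CMC-1 variable); `mode = "count"` sums the rare-variant dosages (the
#' CMC-count variable). An empty rare index set yields an all-zero variable
#' flagged as degenerate rather than an error, so genes without polymorphic
#' rare variants stay in the bookkeeping.
#'
#' @param g a [genotype_matrix()] (missing dosages should be imputed first;
#'   see [impute_mean()]).
#' @param rare integer vector of rare-variant column indices.
#' @param mode `"indicator"` or `"count"`.
#' @return A `collapsed_variable`: list with `values` (length = sample
#'   count), `mode`, `variants`, `degenerate`.
#' @export
cmc_collapse <- function(g, rare, mode = c("indicator", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "genotype_matrix"))
  n <- length(g$sample_ids)
  if (length(rare) == 0) {
    return(collapsed_variable(numeric(n), mode, integer(0), degenerate = TRUE))
  }
  sub <- g$dosages[, rare, drop = FALSE]
  vals <- rowSums(sub)
  if (mode == "indicator") vals <- as.numeric(vals > 0)
  collapsed_variable(vals, mode, as.integer(rare))
}

#' Collapse variants into a frequency-weighted sum
#'
#' Weighted-sum collapse for a quantitative-trait sample: for variant `j`
#' with `m_j` minor alleles observed over `n` genotyped individuals, the
#' pseudo-count frequency is `q_j = (m_j + 1) / (2n + 2)` and the weight
#' `w_j = sqrt(n * q_j * (1 - q_j))`; each individual's score is the sum of
#' dosages divided by their variant's weight, so rarer alleles contribute
#' more. The pseudo-count keeps every weight strictly positive.
#'
#' @inheritParams cmc_collapse
#' @param variants integer vector of variant column indices (all variants of
#'   the gene, rare and common).
#' @return A `collapsed_variable` with `mode = "weighted_sum"` and a
#'   `weights` element.
#' @export
weighted_sum_collapse <- function(g, variants) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- length(g$sample_ids)
  if (length(variants) == 0) {
    return(collapsed_variable(numeric(n), "weighted_sum", integer(0),
                              degenerate = TRUE))
  }
  sub <- g$dosages[, variants, drop = FALSE]
  m <- colSums(sub)
  q <- (m + 1) / (2 * n + 2)
  w <- sqrt(n * q * (1 - q))
  out <- collapsed_variable(drop(sub %*% (1 / w)), "weighted_sum",
                            as.integer(variants))
  out$weights <- w
  out
}

collapsed_variable <- function(values, mode, variants, degenerate = FALSE) {
  if (mode == "indicator") stopifnot(all(values %in% c(0, 1)))
  if (mode == "count") stopifnot(all(values >= 0))
  structure(
    list(values = as.numeric(values), mode = mode,
         variants = variants, degenerate = degenerate),
    class = "collapsed_variable"
  )
}

#' @export
print.collapsed_variable <- function(x, ...) {
  cat("<collapsed_variable> mode=", x$mode, ", ", length(x$values),
      " individuals, ", length(x$variants), " variant(s)",
      if (x$degenerate) ", DEGENERATE", "\n", sep = "")
  invisible(x)
}

#' A reproducible phenotype-permutation plan
#'
#' Generates `B` random permutations of the sample indices from a fixed seed.
#' One plan is shared across all genes and tests of an analysis so that each
#' permutation applies the same reshuffled phenotype to every gene,
#' preserving inter-gene correlation in the permutation null — the property
#' the set-enrichment null distribution relies on.
#'
#' @param n_samples number of individuals.
#' @param B number of permutations (default 2000).
#' @param seed integer seed.
#' @return A `permutation_plan`: list with `B`, `seed`, `n`, and `perms`, a
#'   `B x n` integer matrix whose rows are permutations.
#' @export
permutation_plan <- function(n_samples, B = 2000, seed = 1L) {
  stopifnot(n_samples >= 2, B >= 1)
  perms <- withr::with_seed(seed,
    t(replicate(B, sample.int(n_samples)))
  )
  structure(list(B = as.integer(B), seed = as.integer(seed),
                 n = as.integer(n_samples), perms = perms,
                 exhaustive = FALSE),
            class = "permutation_plan")
}

#' Exhaustive permutation plan (small n)
#'
#' Enumerates all `n!` permutations; used to validate permutation p-values
#' exactly for tiny samples.
#'
#' @param n_samples number of individuals (must be <= 7).
#' @return A `permutation_plan` whose rows enumerate every permutation.
#' @export
exhaustive_plan <- function(n_samples) {
  stopifnot(n_samples >= 2, n_samples <= 7)
  perms <- permutations_all(n_samples)
  structure(list(B = nrow(perms), seed = NA_integer_,
                 n = as.integer(n_samples), perms = perms,
                 exhaustive = TRUE),
            class = "permutation_plan")
}

permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(rep(k, nrow(sub)), sub + (sub >= k))
  }))
}

#' CMC regression test for one gene
#'
#' Fits ordinary least squares of the trait on an intercept, the collapsed
#' rare-variant variable, and each common variant of the gene, and reports
#' the joint F-test of all genetic coefficients against the intercept-only
#' model as the gene-level p-value. Constant columns are dropped; if nothing
#' genetic remains (or the trait is constant) the result is degenerate with
#' p = 1.
#'
#' @param y numeric phenotype vector aligned to `g` (see
#'   [align_phenotype()]).
#' @param collapsed a `collapsed_variable` from [cmc_collapse()].
#' @param common integer indices of the gene's common variants.
#' @param g a [genotype_matrix()] with no missing dosages.
#' @param gene gene label for the result.
#' @return A one-row tibble: `gene`, `test`, `statistic` (F), `p_analytic`,
#'   `df1`, `df2`, `n`, `degenerate`.
#' @export
cmc_test <- function(y, collapsed, common, g, gene = NA_character_) {
  test_name <- if (collapsed$mode == "indicator") "CMC-1" else "CMC-count"
  X <- cbind(collapsed$values,
             if (length(common)) g$dosages[, common, drop = FALSE])
  res <- ols_joint_f(y, X)
  tibble::tibble(
    gene = gene, test = test_name, statistic = res$statistic,
    p_analytic = res$p, df1 = res$df1, df2 = res$df2,
    n = length(y), degenerate = res$degenerate
  )
}

# Joint F of y ~ 1 + X vs y ~ 1, with constant columns dropped.
ols_joint_f <- function(y, X) {
  n <- length(y)
  if (stats::sd(y) == 0) {
    return(list(statistic = 0, p = 1, df1 = 0L, df2 = n - 1L, degenerate = TRUE))
  }
  X <- as.matrix(X)
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) {
    return(list(statistic = 0, p = 1, df1 = 0L, df2 = n - 1L, degenerate = TRUE))
  }
  qrX <- qr(cbind(1, X))
  k <- qrX$rank - 1L          # genetic df after dropping collinear columns
  if (k < 1L) {
    return(list(statistic = 0, p = 1, df1 = 0L, df2 = n - 1L, degenerate = TRUE))
  }
  if (n < qrX$rank + 1L) stop("fewer individuals than design columns + 1",
                              call. = FALSE)
  fit <- qr.fitted(qrX, y)
  rss <- sum((y - fit)^2)
  tss <- sum((y - mean(y))^2)
  df2 <- n - qrX$rank
  f <- ((tss - rss) / k) / (rss / df2)
  p <- stats::pf(f, k, df2, lower.tail = FALSE)
  list(statistic = f, p = p, df1 = k, df2 = df2, degenerate = FALSE)
}

#' Permutation cross-product test (WeightSum1)
#'
#' Tests association between a collapsed score and the trait with the
#' absolute centered cross product `T = |sum_i (s_i - s_bar)(y_i - y_bar)|`,
#' assessed against phenotype permutations:
#' `p = (1 + #\{b : T_b >= T\}) / (B + 1)`. With an [exhaustive_plan()] the
#' exact enumeration p `#\{b : T_b >= T\} / n!` is reported instead (the
#' enumeration already contains the identity permutation).
#'
#' @param y numeric phenotype vector.
#' @param s a `collapsed_variable` (typically from
#'   [weighted_sum_collapse()]).
#' @param plan a [permutation_plan()] (or [exhaustive_plan()] for exact p).
#' @param gene gene label for the result.
#' @return One-row tibble: `gene`, `test`, `statistic`, `p_permutation`,
#'   `B`, `n`, `degenerate`.
#' @export
weightsum1_test <- function(y, s, plan, gene = NA_character_) {
  sv <- s$values
  degen <- s$degenerate || stats::sd(sv) == 0 || stats::sd(y) == 0
  if (degen) {
    return(tibble::tibble(gene = gene, test = "WeightSum1", statistic = 0,
                          p_permutation = 1, B = plan$B, n = length(y),
                          degenerate = TRUE))
  }
  t_obs <- ws1_stat(sv, y)
  t_perm <- ws1_stat(sv, y, plan$perms)
  # permutations that only reshuffle individuals with equal collapsed
  # scores are mathematically tied with the observed cross product but can
  # differ by an ulp; count them as >= via a relative tolerance
  n_ge <- sum(t_perm >= t_obs - 1e-9 * t_obs)
  # an exhaustive plan already contains the identity permutation, so the
  # exact enumeration p needs no add-one correction
  p <- if (isTRUE(plan$exhaustive)) n_ge / plan$B
       else (1 + n_ge) / (plan$B + 1)
  tibble::tibble(gene = gene, test = "WeightSum1", statistic = t_obs,
                 p_permutation = p, B = plan$B, n = length(y),
                 degenerate = FALSE)
}

ws1_stat <- function(s, y, perms = NULL) {
  sc <- s - mean(s)
  yc <- y - mean(y)
  if (is.null(perms)) return(abs(sum(sc * yc)))
  abs(as.vector(matrix(yc[t(perms)], ncol = nrow(perms)) |> crossprod(sc)))
}

#' Simple-regression test of the collapsed score (WeightSum2)
#'
#' Regresses the trait on the collapsed score and reports the two-sided
#' t-test p-value for the slope.
#'
#' @inheritParams weightsum1_test
#' @return One-row tibble: `gene`, `test`, `statistic` (slope t), `p_analytic`,
#'   `n`, `degenerate`.
#' @export
weightsum2_test <- function(y, s, gene = NA_character_) {
  sv <- s$values
  n <- length(y)
  if (s$degenerate || stats::sd(sv) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(gene = gene, test = "WeightSum2", statistic = 0,
                          p_analytic = 1, n = n, degenerate = TRUE))
  }
  sc <- sv - mean(sv)
  yc <- y - mean(y)
  beta <- sum(sc * yc) / sum(sc^2)
  rss <- sum((yc - beta * sc)^2)
  se <- sqrt(rss / (n - 2) / sum(sc^2))
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  tibble::tibble(gene = gene, test = "WeightSum2", statistic = tstat,
                 p_analytic = p, n = n, degenerate = FALSE)
}
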