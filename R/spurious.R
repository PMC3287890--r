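#' Flag spurious genes from replicate p-values
#'
#' A spurious gene is a non-risk gene that keeps turning up significant
#' across phenotype replicates — typically because long-distance correlation
#' ties its genotypes to a true risk gene. A non-risk gene is flagged when
#' its gene-level p-value falls strictly below `alpha` in at least
#' `min_hits` of the replicates. Risk genes are never flagged. With 200
#' replicates and `alpha = 0.05` the conventional cutoff is 16 hits;
#' [default_min_hits()] generalizes that rule to other replicate counts.
#'
#' @param p_matrix numeric replicates x genes matrix of gene-level p-values
#'   (column names = gene ids), e.g. built from repeated [run_step1()] calls.
#' @param risk_genes character vector of known risk genes (excluded from
#'   flagging).
#' @param alpha per-replicate significance level, default 0.05 (strict `<`).
#' @param min_hits minimum number of significant replicates; default derived
#'   from `nrow(p_matrix)` and `alpha` by [default_min_hits()], which gives
#'   16 when there are 200 replicates at `alpha = 0.05`.
#' @return Character vector of flagged (spurious) gene ids.
#' @export
identify_spurious <- function(p_matrix, risk_genes = character(),
                              alpha = 0.05, min_hits = NULL) {
  stopifnot(is.matrix(p_matrix), !is.null(colnames(p_matrix)),
            alpha > 0, alpha < 1)
  R <- nrow(p_matrix)
  if (is.null(min_hits)) min_hits <- default_min_hits(R, alpha)
  if (min_hits < 1 || min_hits > R) {
    stop("min_hits must be between 1 and the number of replicates (", R, ")",
         call. = FALSE)
  }
  hits <- colSums(p_matrix < alpha)
  flagged <- colnames(p_matrix)[hits >= min_hits]
  setdiff(flagged, risk_genes)
}

#' Replicate-count threshold for the spurious-gene rule
#'
#' The smallest hit count `k` whose probability under the binomial null —
#' every replicate an independent `alpha`-level coin flip — is at most
#' `tail`: the least `k` with `P(Bin(R, alpha) >= k) <= tail`, clamped to at
#' least 1. The default `tail` of 0.05 reproduces the conventional 16-of-200
#' cutoff at `alpha = 0.05` (whose implied tail probability is about 0.037).
#'
#' @param R number of replicates.
#' @param alpha per-replicate significance level.
#' @param tail maximum binomial tail probability for a chance flag.
#' @return Integer threshold `k`.
#' @export
default_min_hits <- function(R, alpha = 0.05, tail = 0.05) {
  stopifnot(R >= 1, alpha > 0, alpha < 1, tail > 0, tail <= 1)
  # P(Bin >= k) <= tail  <=>  k >= qbinom(1 - tail, ...) + 1 adjusted for ties
  k <- 0L
  repeat {
    if (stats::pbinom(k - 1, R, alpha, lower.tail = FALSE) <= tail) break
    k <- k + 1L
    if (k > R) break
  }
  max(1L, min(k, R))
}

#' Remove genes from a panel, map, or set collection
#'
#' Drops the listed genes from every gene-indexed field of the object —
#' score vectors and permutation columns of a `gene_score_panel` (or each
#' panel of a `step1_result`), entries of a `gene_map`, members of a
#' `gene_set_collection` — recording the removal in an `excluded` attribute.
#' Unknown genes warn rather than error; excluding nothing is the identity.
#'
#' @param x a `gene_score_panel`, `step1_result`, `gene_map`, or
#'   `gene_set_collection`.
#' @param genes character vector of genes to remove.
#' @return The filtered object.
#' @export
exclude_genes <- function(x, genes) {
  UseMethod("exclude_genes")
}

check_known <- function(known, genes) {
  unknown <- setdiff(genes, known)
  if (length(unknown)) {
    warning("ignoring unknown gene(s): ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ...", call. = FALSE)
  }
  intersect(genes, known)
}

#' @export
exclude_genes.gene_score_panel <- function(x, genes) {
  genes <- check_known(x$genes, genes)
  if (length(genes) == 0) return(x)
  keep <- !(x$genes %in% genes)
  x$genes <- x$genes[keep]
  for (f in c("stat_obs", "p_analytic", "p_permutation", "score_obs",
              "degenerate")) {
    x[[f]] <- x[[f]][keep]
  }
  for (f in c("stat_perm", "p_perm_rows", "score_perm")) {
    x[[f]] <- x[[f]][, keep, drop = FALSE]
  }
  attr(x, "excluded") <- union(attr(x, "excluded"), genes)
  x
}

#' @export
exclude_genes.step1_result <- function(x, genes) {
  out <- lapply(x, exclude_genes, genes = genes)
  structure(out, class = class(x))
}

#' @export
exclude_genes.gene_map <- function(x, genes) {
  genes <- check_known(names(x), genes)
  out <- x[setdiff(names(x), genes)]
  structure(out, class = class(x),
            excluded = union(attr(x, "excluded"), genes))
}

#' @export
exclude_genes.gene_set_collection <- function(x, genes) {
  genes <- check_known(unique(unlist(x, use.names = FALSE)), genes)
  if (length(genes) == 0) return(x)
  old_sizes <- lengths(x)
  sets <- lapply(x, setdiff, y = genes)
  shrunk <- lengths(sets) < old_sizes
  if (any(shrunk)) {
    message("gene sets shrunk by exclusion: ",
            paste0(names(x)[shrunk], " (", old_sizes[shrunk], " -> ",
                   lengths(sets)[shrunk], ")", collapse = ", "))
  }
  keep <- lengths(sets) >= 1
  if (any(!keep)) {
    warning("set(s) emptied by exclusion dropped: ",
            paste(names(x)[!keep], collapse = ", "), call. = FALSE)
  }
  structure(sets[keep],
            descriptions = attr(x, "descriptions")[keep],
            excluded = union(attr(x, "excluded"), genes),
            class = class(x))
}
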