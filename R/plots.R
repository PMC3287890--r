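#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Power-versus-perturbation curve
#'
#' Plots the experiment's power against the perturbation of the risk gene
#' set (negative: risk genes removed, 0: intact set, positive: noise genes
#' added), one line per enrichment method, dashed when spurious genes are
#' left in, faceted by gene-level test.
#'
#' @param object a `burden_experiment` from [run_experiment()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.burden_experiment <- function(object, ...) {
  df <- object$power_curve
  if (nrow(df) == 0) stop("experiment has no power conditions to plot",
                          call. = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$perturbation, y = .data$rate, colour = .data$method,
    linetype = .data$spurious_excluded
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene_test)) +
    ggplot2::scale_linetype_manual(
      values = c(`TRUE` = "solid", `FALSE` = "dashed"),
      labels = c(`TRUE` = "excluded", `FALSE` = "present"),
      name = "spurious genes"
    ) +
    ggplot2::labs(
      x = "gene-set perturbation (risk genes removed ← 0 → noise genes added)",
      y = paste0("power at α = ", object$alpha),
      colour = "enrichment"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Gene-score null diagnostics
#'
#' Shows, for a sample of genes, the gene's permutation score distribution
#' with the observed score overlaid — the heterogeneity across genes is what
#' the permutation standardization removes.
#'
#' @param object a `gene_score_panel`.
#' @param genes genes to display; default the 12 with the largest observed
#'   scores.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gene_score_panel <- function(object, genes = NULL, ...) {
  if (is.null(genes)) {
    genes <- object$genes[order(-object$score_obs)][
      seq_len(min(12, length(object$genes)))]
  }
  perm <- tibble::tibble(
    gene = rep(genes, each = object$B),
    score = as.vector(object$score_perm[, genes, drop = FALSE])
  )
  obs <- tibble::tibble(gene = genes,
                        score = unname(object$score_obs[genes]))
  ggplot2::ggplot(perm, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$score),
                        colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene), scales = "free") +
    ggplot2::labs(
      x = if (isTRUE(object$adjusted)) "standardized gene score"
          else "gene score (-log10 p)",
      y = "permutations",
      title = paste0(object$test, " gene scores vs their permutation null")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
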