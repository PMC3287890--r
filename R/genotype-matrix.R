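#' Construct a genotype dosage matrix
#'
#' A `genotype_matrix` holds minor-allele dosages (0, 1, 2, or `NA`) for a
#' set of individuals (rows) by variants (columns), together with sample and
#' variant identifiers and the per-variant minor allele frequency (MAF).
#' Dosages are always coded on the minor allele, i.e. the allele whose sample
#' frequency is at most 0.5, so a dosage of 2 means two copies of the rarer
#' allele regardless of which allele a source VCF called the reference.
#'
#' @param dosages numeric matrix of minor-allele counts, individuals x
#'   variants; entries must be 0, 1, 2 or `NA`.
#' @param sample_ids character vector of row identifiers; defaults to the
#'   matrix rownames or `S1..Sn`.
#' @param variant_ids character vector of column identifiers; defaults to the
#'   matrix colnames or `V1..Vm`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `sample_ids`, `variant_ids`, and `variant_maf` (recomputed
#'   from the dosages).
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 0), nrow = 2))
#' g$variant_maf
genotype_matrix <- function(dosages, sample_ids = NULL, variant_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  bad <- !is.na(dosages) & !dosages %in% c(0, 1, 2)
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or NA; found ",
         paste(unique(dosages[bad]), collapse = ", "), call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages) %||% paste0("S", seq_len(nrow(dosages)))
  }
  if (is.null(variant_ids)) {
    variant_ids <- colnames(dosages) %||% paste0("V", seq_len(ncol(dosages)))
  }
  if (length(sample_ids) != nrow(dosages)) {
    stop("length(sample_ids) != nrow(dosages)", call. = FALSE)
  }
  if (length(variant_ids) != ncol(dosages)) {
    stop("length(variant_ids) != ncol(dosages)", call. = FALSE)
  }
  if (anyDuplicated(variant_ids)) {
    stop("variant_ids must be unique", call. = FALSE)
  }
  dimnames(dosages) <- list(sample_ids, variant_ids)
  out <- structure(
    list(
      dosages = dosages,
      sample_ids = as.character(sample_ids),
      variant_ids = as.character(variant_ids),
      variant_maf = NULL
    ),
    class = "genotype_matrix"
  )
  out$variant_maf <- compute_maf(out)
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$sample_ids), " individuals x ",
      length(x$variant_ids), " variants\n", sep = "")
  if (length(x$variant_maf)) {
    rng <- range(x$variant_maf, na.rm = TRUE)
    cat("  MAF range: [", signif(rng[1], 3), ", ", signif(rng[2], 3), "]\n",
        sep = "")
  }
  n_mis <- sum(is.na(x$dosages))
  if (n_mis > 0) cat("  missing dosages:", n_mis, "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Per-variant minor allele frequency
#'
#' Computes, for each variant column, the frequency of the minor allele over
#' the non-missing genotypes: with `f` the dosage-allele frequency
#' (mean dosage / 2), MAF = min(f, 1 - f), always in \[0, 0.5\]. Variants with
#' no non-missing calls get `NA` with a warning.
#'
#' @param g a [genotype_matrix()].
#' @return Named numeric vector of MAFs, one per variant.
#' @export
compute_maf <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  f <- colMeans(g$dosages, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  all_missing <- colSums(!is.na(g$dosages)) == 0
  if (any(all_missing)) {
    warning("MAF undefined for all-missing variant(s): ",
            paste(g$variant_ids[all_missing], collapse = ", "), call. = FALSE)
    maf[all_missing] <- NA_real_
  }
  names(maf) <- g$variant_ids
  maf
}

#' Split a gene's variants into rare and common
#'
#' Partitions the variant columns of one gene by MAF: rare means
#' MAF <= `maf_threshold` (inclusive), common is the rest. Monomorphic
#' variants (MAF exactly 0, which carry no association information) are
#' excluded from both groups and reported separately.
#'
#' @param g a [genotype_matrix()].
#' @param gene_map a gene map as returned by [read_gene_map()] or
#'   [as_gene_map()]: a named list of integer column indices into `g`.
#' @param gene gene identifier to look up in `gene_map`.
#' @param maf_threshold rare/common MAF boundary in (0, 0.5]; default 0.01.
#'
#' @return A list with integer index vectors `rare`, `common`, `monomorphic`
#'   (columns of `g`).
#' @export
partition_variants <- function(g, gene_map, gene, maf_threshold = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"),
            maf_threshold > 0, maf_threshold <= 0.5)
  if (!gene %in% names(gene_map)) {
    stop("gene not found in gene map: ", gene, call. = FALSE)
  }
  idx <- gene_map[[gene]]
  maf <- g$variant_maf[idx]
  mono <- which(!is.na(maf) & maf == 0)
  rare <- which(!is.na(maf) & maf > 0 & maf <= maf_threshold)
  common <- which(!is.na(maf) & maf > maf_threshold)
  list(rare = idx[rare], common = idx[common], monomorphic = idx[mono])
}

#' Validate and normalize a gene-to-variant map
#'
#' @param x named list mapping gene id to variant ids (character) or column
#'   indices (integer) of the companion genotype matrix.
#' @param g the companion [genotype_matrix()].
#' @return Named list of integer column indices, class `gene_map`.
#' @export
as_gene_map <- function(x, g) {
  stopifnot(inherits(g, "genotype_matrix"), is.list(x), !is.null(names(x)))
  out <- lapply(x, function(v) {
    if (is.character(v)) {
      idx <- match(v, g$variant_ids)
      if (anyNA(idx)) {
        stop("unknown variant id(s): ", paste(v[is.na(idx)], collapse = ", "),
             call. = FALSE)
      }
    } else {
      idx <- as.integer(v)
      if (any(idx < 1L | idx > length(g$variant_ids))) {
        stop("variant index out of range", call. = FALSE)
      }
    }
    if (anyDuplicated(idx)) stop("duplicate variant within a gene", call. = FALSE)
    idx
  })
  structure(out, class = c("gene_map", "list"))
}

#' Mean-impute missing dosages
#'
#' Replaces missing dosages by the per-variant mean dosage over observed
#' calls, so regression design matrices stay full rank without dropping
#' individuals. MAFs are unchanged (they are computed over observed calls).
#'
#' @param g a [genotype_matrix()].
#' @return The genotype matrix with no missing dosages; a message reports how
#'   many cells were imputed.
#' @export
impute_mean <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_mis <- sum(is.na(g$dosages))
  if (n_mis == 0) return(g)
  mu <- colMeans(g$dosages, na.rm = TRUE)
  for (j in which(colSums(is.na(g$dosages)) > 0)) {
    g$dosages[is.na(g$dosages[, j]), j] <- mu[j]
  }
  message("mean-imputed ", n_mis, " missing dosage(s)")
  g
}
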