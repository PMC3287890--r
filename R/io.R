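#' Read genotypes from VCF or a dosage table
#'
#' Two dialects are supported. `format = "vcf"` reads a VCF (v4.x) with
#' diploid GT fields through the vcfR package; alternate-allele dosages are
#' counted, then each variant is re-oriented to the sample minor allele (the
#' allele with frequency <= 0.5; a tie at exactly 0.5 keeps the ALT coding).
#' `format = "table"` reads a TSV with a header row of variant ids, the first
#' column holding sample ids, and cells in \{0, 1, 2, NA\}; table dosages are
#' taken as given (the dialect stores minor-allele dosages directly), so a
#' write/read round trip is exact.
#'
#' @param path file path.
#' @param format `"vcf"` or `"table"`; default guesses from the extension.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "table", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "table"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    vcf = read_genotypes_vcf(path),
    table = read_genotypes_table(path)
  )
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || nrow(gt) == 0) {
    stop("VCF has no GT genotypes: ", path, call. = FALSE)
  }
  alleles <- gsub("\\|", "/", gt)
  parts <- strsplit(as.vector(alleles), "/", fixed = TRUE)
  n_alleles <- lengths(parts)
  bad <- !is.na(as.vector(gt)) & n_alleles != 2L
  if (any(bad)) {
    stop("non-diploid GT field(s) in VCF (first at variant ",
         rownames(gt)[(which(bad)[1] - 1) %% nrow(gt) + 1], ")",
         call. = FALSE)
  }
  count_alt <- function(p) {
    if (length(p) != 2L || any(p == ".")) return(NA_real_)
    sum(p != "0")
  }
  dos <- matrix(vapply(parts, count_alt, numeric(1)),
                nrow = nrow(gt), dimnames = dimnames(gt))
  dos <- t(dos)  # individuals x variants
  fix <- vcf@fix
  vid <- fix[, "ID"]
  no_id <- is.na(vid) | vid == "."
  vid[no_id] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[no_id]
  colnames(dos) <- vid
  # orient to the minor allele; ties at 0.5 keep ALT counts
  f_alt <- colMeans(dos, na.rm = TRUE) / 2
  flip <- !is.na(f_alt) & f_alt > 0.5
  dos[, flip] <- 2 - dos[, flip]
  genotype_matrix(dos)
}

read_genotypes_table <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(tab) < 2) stop("genotype table needs a sample column plus >=1 variant", call. = FALSE)
  sample_ids <- tab[[1]]
  cells <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells),
                                 dimnames = dimnames(cells)))
  bad_cell <- !is.na(cells) & cells != "NA" & (is.na(num) | !num %in% c(0, 1, 2))
  if (any(bad_cell)) {
    ij <- which(bad_cell, arr.ind = TRUE)[1, ]
    stop("invalid dosage '", cells[bad_cell][1], "' at line ", ij[1] + 1,
         " (variant ", colnames(cells)[ij[2]], ") of ", path, call. = FALSE)
  }
  genotype_matrix(num, sample_ids = sample_ids)
}

#' Write genotypes in the dosage-table dialect
#'
#' @param g a [genotype_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- tibble::as_tibble(g$dosages)
  tab <- dplyr::bind_cols(tibble::tibble(sample_id = g$sample_ids), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a gene-to-variant map
#'
#' TSV with columns `gene` and `variant_id`; variant ids are resolved against
#' the companion genotype matrix.
#'
#' @param path TSV path.
#' @param g the companion [genotype_matrix()].
#' @return A `gene_map` (named list of column indices).
#' @export
read_gene_map <- function(path, g) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), variant_id = readr::col_character()
  ), progress = FALSE)
  as_gene_map(split(tab$variant_id, tab$gene), g)
}

#' Write a gene map as TSV
#' @param gene_map a `gene_map`.
#' @param g the companion [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(gene_map, g, path) {
  tab <- tibble::tibble(
    gene = rep(names(gene_map), lengths(gene_map)),
    variant_id = g$variant_ids[unlist(gene_map, use.names = FALSE)]
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a quantitative phenotype
#'
#' TSV with columns `sample_id` and `value`.
#'
#' @param path TSV path.
#' @return Tibble with columns `sample_id`, `value`.
#' @export
read_phenotype <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), value = readr::col_double()
  ), progress = FALSE)
}

#' Align a phenotype to a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param phenotype tibble with `sample_id`, `value`, or a bare numeric vector
#'   already in `g`'s sample order.
#' @return Numeric vector ordered as `g$sample_ids`.
#' @export
align_phenotype <- function(g, phenotype) {
  if (is.numeric(phenotype)) {
    if (length(phenotype) != length(g$sample_ids)) {
      stop("phenotype length does not match sample count", call. = FALSE)
    }
    return(as.numeric(phenotype))
  }
  stopifnot(is.data.frame(phenotype),
            all(c("sample_id", "value") %in% names(phenotype)))
  idx <- match(g$sample_ids, phenotype$sample_id)
  if (anyNA(idx)) {
    stop("phenotype missing sample(s): ",
         paste(utils::head(g$sample_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  as.numeric(phenotype$value[idx])
}

#' Read gene sets from a GMT file
#'
#' One set per line: tab-separated name, description, then member genes.
#' Duplicate members within a line are dropped with a warning; a line with
#' fewer than three fields is a format error reported with its line number.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1], " has fewer than 3 tab-separated fields",
         call. = FALSE)
  }
  sets <- lapply(seq_along(fields), function(i) {
    members <- fields[[i]][-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicate gene(s) in set '", fields[[i]][1],
              "' (GMT line ", i, "); keeping unique members", call. = FALSE)
      members <- unique(members)
    }
    members
  })
  names(sets) <- vapply(fields, `[`, character(1), 1)
  desc <- vapply(fields, `[`, character(1), 2)
  gene_set_collection(sets, descriptions = desc)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (unique members, size >= 1
#'   each, unless the collection is empty).
#' @param descriptions optional character vector, one per set.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets))
  if (length(sets)) {
    stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
    if (any(lengths(sets) < 1L)) stop("empty gene set", call. = FALSE)
    if (any(vapply(sets, anyDuplicated, integer(1)) > 0)) {
      stop("duplicate members within a set", call. = FALSE)
    }
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  stopifnot(length(descriptions) == length(sets))
  structure(sets, descriptions = descriptions,
            class = c("gene_set_collection", "list"))
}

#' Write gene sets as GMT
#' @param sets a `gene_set_collection` or named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% rep("", length(sets))
  desc[!nzchar(desc)] <- "na"
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", length(x), " set(s)\n", sep = "")
  if (length(x)) {
    sz <- lengths(x)
    cat("  sizes: min ", min(sz), ", median ", stats::median(sz),
        ", max ", max(sz), "\n", sep = "")
  }
  invisible(x)
}

#' @export
#' @method as_tibble gene_set_collection
as_tibble.gene_set_collection <- function(x, ...) {
  tibble::tibble(
    set = rep(names(x), lengths(x)),
    gene = unlist(x, use.names = FALSE)
  )
}
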