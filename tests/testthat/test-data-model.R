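write_vcf <- function(path, samples, gt_rows, alt = "T") {
  # gt_rows: list of character vectors, one GT per sample per site
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_along(gt_rows), function(i) {
    paste(c("1", 100 + i, paste0("rs", i), "A", alt, ".", "PASS", ".",
            "GT", gt_rows[[i]]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

test_that("VCF dosages are coded on the minor allele", {
  p <- write_vcf(withr::local_tempfile(fileext = ".vcf"),
                 c("A", "B", "C"), list(c("0/0", "0/1", "1/1")))
  g <- read_genotypes(p, format = "vcf")
  # ALT frequency exactly 0.5: tie breaks toward ALT
  expect_equal(unname(g$dosages[, 1]), c(0, 1, 2))
  expect_equal(unname(g$variant_maf), 0.5)

  # ALT frequency 0.8: REF is the minor allele, so REF copies are counted
  p2 <- write_vcf(withr::local_tempfile(fileext = ".vcf"),
                  c("A", "B", "C", "D", "E"),
                  list(c("1/1", "1/1", "1/1", "1/0", "0/1")))
  g2 <- read_genotypes(p2, format = "vcf")
  expect_equal(unname(g2$dosages[, 1]), c(0, 0, 0, 1, 1))
  expect_equal(unname(g2$variant_maf), 0.2)

  # missing and phased genotypes
  p3 <- write_vcf(withr::local_tempfile(fileext = ".vcf"),
                  c("A", "B", "C"), list(c("./.", "0|1", "0/0")))
  g3 <- read_genotypes(p3, format = "vcf")
  expect_true(is.na(g3$dosages["A", 1]))
  expect_equal(unname(g3$dosages[c("B", "C"), 1]), c(1, 0))
})

test_that("non-diploid GT fields are a format error", {
  p <- write_vcf(withr::local_tempfile(fileext = ".vcf"),
                 c("A", "B"), list(c("0/1/1", "0/0")))
  expect_error(read_genotypes(p, format = "vcf"), "non-diploid")
})

test_that("table round trip reproduces dosages and MAFs exactly", {
  set.seed(7)
  dos <- matrix(sample(c(0, 1, 2, NA), 60, replace = TRUE,
                       prob = c(.6, .2, .1, .1)), nrow = 10)
  g <- gm(dos)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path, format = "table")
  expect_identical(g2$dosages, g$dosages)
  expect_identical(g2$variant_maf, g$variant_maf)
  expect_identical(g2$sample_ids, g$sample_ids)
})

test_that("table reader flags invalid cells with their line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tV1\tV2", "S1\t0\t1", "S2\t3\t0"), path)
  expect_error(read_genotypes(path, format = "table"), "line 3")
  writeLines(c("sample_id\tV1", "S1\t0", "S2\tNA"), path)
  g <- read_genotypes(path, format = "table")
  expect_true(is.na(g$dosages[2, 1]))
})

test_that("compute_maf matches a brute-force allele tally", {
  expect_equal(unname(compute_maf(gm(matrix(c(0, 1, 2, 1))))), 0.5)
  expect_equal(unname(compute_maf(gm(matrix(c(0, 0, 0, 1))))), 0.125)
  expect_equal(unname(compute_maf(gm(matrix(rep(2, 5))))), 0)
  expect_equal(unname(compute_maf(gm(matrix(0, 4, 3)))), rep(0, 3))
  for (seed in 1:5) {
    set.seed(seed)
    dos <- matrix(sample(c(0, 1, 2, NA), 80, replace = TRUE), nrow = 8)
    dos[1, ] <- 0  # ensure at least one non-missing call per variant
    g <- gm(dos)
    expect_equal(unname(g$variant_maf), unname(brute_maf(dos)))
  }
  g_allmiss <- suppressWarnings(gm(matrix(NA_real_, 3, 1)))
  expect_warning(compute_maf(g_allmiss), "all-missing")
})

test_that("partition_variants splits rare/common/monomorphic correctly", {
  # engineer MAFs [0.005, 0.2, 0.01] over 100 individuals
  dos <- cbind(c(1, rep(0, 99)),                       # maf 0.005
               c(rep(1, 40), rep(0, 60)),              # maf 0.2
               c(1, 1, rep(0, 98)))                    # maf 0.01
  g <- gm(dos)
  gmap <- as_gene_map(list(gene1 = 1:3), g)
  part <- partition_variants(g, gmap, "gene1", maf_threshold = 0.01)
  expect_equal(part$rare, c(1L, 3L))   # threshold is inclusive
  expect_equal(part$common, 2L)
  expect_equal(part$monomorphic, integer(0))

  # all common
  g2 <- gm(cbind(rep(c(0, 1, 2), 10), rep(c(2, 1, 0), 10)))
  m2 <- as_gene_map(list(a = 1:2), g2)
  p2 <- partition_variants(g2, m2, "a")
  expect_equal(p2$rare, integer(0))
  expect_equal(p2$common, 1:2)

  # monomorphic dropped from both partitions
  g3 <- gm(cbind(rep(0, 200), c(1, rep(0, 199))))
  m3 <- as_gene_map(list(a = 1:2), g3)
  p3 <- partition_variants(g3, m3, "a")
  expect_equal(p3$monomorphic, 1L)
  expect_equal(p3$rare, 2L)
  expect_equal(p3$common, integer(0))

  expect_error(partition_variants(g3, m3, "nope"), "not found")
})

test_that("partition is exhaustive and disjoint on random genes", {
  set.seed(11)
  for (i in 1:10) {
    study <- tiny_study(n = 60, n_genes = 6, causal = 0, h2 = 0, seed = i)
    g <- study$genotypes
    for (gene in names(study$gene_map)) {
      part <- partition_variants(g, study$gene_map, gene)
      all_idx <- sort(c(part$rare, part$common, part$monomorphic))
      expect_equal(all_idx, sort(study$gene_map[[gene]]))
      expect_length(intersect(part$rare, part$common), 0)
    }
  }
})

test_that("GMT files parse, deduplicate, and error informatively", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("Q2set\tdesc\tVNN1\tVNN3",
               "dup\tdesc\tVNN1\tVNN1\tBCHE"), path)
  expect_warning(sets <- read_gene_sets(path), "duplicate")
  expect_named(sets, c("Q2set", "dup"))
  expect_length(sets$Q2set, 2)
  expect_setequal(sets$dup, c("VNN1", "BCHE"))

  writeLines(c("ok\td\tA\tB", "bad\tonly-two-fields"), path)
  expect_error(read_gene_sets(path), "line 2")

  writeLines(character(0), path)
  empty <- read_gene_sets(path)
  expect_s3_class(empty, "gene_set_collection")
  expect_length(empty, 0)
})

test_that("GMT parsing agrees with fgsea's reader", {
  skip_if_not_installed("fgsea")
  path <- withr::local_tempfile(fileext = ".gmt")
  sets <- list(alpha = c("G1", "G2", "G3"), beta = c("G9", "G2"))
  write_gene_sets(gene_set_collection(sets), path)
  ours <- read_gene_sets(path)
  theirs <- fgsea::gmtPathways(path)
  expect_equal(lapply(unclass(ours), identity)[names(theirs)],
               theirs, ignore_attr = TRUE)
})

test_that("gene-map and phenotype TSV round trips and alignment work", {
  study <- tiny_study(n = 30, n_genes = 4, causal = 0, h2 = 0)
  dir <- withr::local_tempdir()
  write_gene_map(study$gene_map, study$genotypes,
                 file.path(dir, "map.tsv"))
  gmap2 <- read_gene_map(file.path(dir, "map.tsv"), study$genotypes)
  expect_equal(unclass(gmap2)[names(study$gene_map)],
               unclass(study$gene_map), ignore_attr = TRUE)

  ph <- study$phenotypes[[1]]
  shuffled <- ph[rev(seq_len(nrow(ph))), ]
  y <- align_phenotype(study$genotypes, shuffled)
  expect_equal(y, ph$value)
  expect_error(align_phenotype(study$genotypes, ph[-1, ]), "missing sample")
})
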