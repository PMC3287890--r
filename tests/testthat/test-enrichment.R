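test_that("score transform is -log10 with clipping", {
  expect_equal(scores_from_pvalues(0.01), 2)
  expect_equal(scores_from_pvalues(1), 0)
  set.seed(1)
  p <- sort(runif(20, 1e-6, 1))
  s <- scores_from_pvalues(p)
  expect_true(all(diff(s) < 0))  # smaller p, larger score
  expect_warning(s0 <- scores_from_pvalues(c(0, 0.5)), "clipped")
  expect_equal(s0[1], 300)
  expect_error(scores_from_pvalues(1.5), "outside")
})

test_that("enrichment score matches the hand-walked example", {
  scores <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  # members are the top 2; exponent 0: running sum peaks at +1 after rank 2
  expect_equal(enrichment_score(scores, c("a", "b"), exponent = 0), 1)
  # bottom-ranked members give the mirrored deficit
  expect_equal(enrichment_score(scores, c("d", "e"), exponent = 0), -1)
  expect_error(enrichment_score(scores, names(scores)), "proper subset")
  expect_error(enrichment_score(scores, character(0)), "proper subset")
  expect_error(enrichment_score(scores, c("a", "zz")), "not in score panel")
})

test_that("enrichment score equals a brute-force running-sum recomputation", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(c(50, 200, 2000), 1)
    scores <- setNames(rexp(n), paste0("g", seq_len(n)))
    if (i %% 2 == 0) scores[sample(n, n / 5)] <- 0  # ties
    members <- sample(names(scores), sample(3:20, 1))
    for (expo in c(0, 1)) {
      expect_equal(enrichment_score(scores, members, expo),
                   brute_es(scores, members, expo))
    }
  }
})

test_that("exponent 0 reduces ES magnitude to the two-sample KS statistic", {
  set.seed(4)
  scores <- setNames(runif(100), paste0("g", 1:100))
  members <- sample(names(scores), 15)
  es <- enrichment_score(scores, members, exponent = 0)
  ranks <- rank(-scores)  # position in the ranked list
  ks <- suppressWarnings(
    stats::ks.test(ranks[members], ranks[setdiff(names(scores), members)])
  )
  expect_equal(abs(es), unname(ks$statistic))
})

test_that("ES of scattered members stays below the random-set null tail", {
  set.seed(10)
  scores <- setNames(rnorm(500), paste0("g", 1:500))
  members <- paste0("g", round(seq(10, 490, length.out = 20)))
  es <- enrichment_score(scores, members, exponent = 0)
  null_es <- vapply(1:500, function(i) {
    enrichment_score(scores, sample(names(scores), 20), exponent = 0)
  }, numeric(1))
  expect_lt(abs(es), quantile(abs(null_es), 0.95))
})

test_that("running-sum statistic agrees with fgsea's implementation", {
  skip_if_not_installed("fgsea")
  set.seed(12)
  for (i in 1:5) {
    scores <- setNames(rexp(80), paste0("g", 1:80))
    members <- sample(names(scores), 10)
    ord <- order(-scores, names(scores))
    es_fgsea <- fgsea::calcGseaStat(
      stats = scores[ord],
      selectedStats = which(names(scores)[ord] %in% members),
      gseaParam = 1
    )
    expect_equal(enrichment_score(scores, members, exponent = 1), es_fgsea,
                 tolerance = 1e-12)
  }
})

# panel with the score track injected directly (statistics double as scores)
make_panel <- function(score_obs, score_perm, genes = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_along(score_obs))
  panel <- gene_score_panel(genes, "CMC-1", score_obs, score_perm)
  panel$score_obs <- stats::setNames(as.numeric(score_obs), genes)
  colnames(score_perm) <- genes
  panel$score_perm <- score_perm
  panel
}

test_that("gsea_test handles the degenerate and maximal extremes", {
  # permutation rows identical to the observed scores -> p = 1
  obs <- c(5, 4, 3, 2, 1, 0.5, 0.2, 0.1)
  panel <- make_panel(obs, matrix(rep(obs, each = 20), nrow = 20))
  r <- gsea_test(panel, c("g1", "g2"))
  expect_equal(r$p, 1)

  # observed member scores at the panel maximum, exchangeable noise rows,
  # B = 199: the observed ES (1, members fill the top ranks) is unreachable
  # by noise rows with 50 genes, so p sits at the floor
  set.seed(2)
  G <- 50
  perm <- matrix(rchisq(199 * G, df = 1), 199, G)
  obs2 <- c(50, 45, 40, 38, 35, rep(0.1, G - 5))
  panel2 <- make_panel(obs2, perm)
  r2 <- gsea_test(panel2, paste0("g", 1:5))
  expect_equal(r2$es, 1)
  expect_equal(r2$p, 1 / 200)
  expect_equal(r2$set_size, 5L)
})

test_that("gsea p-values are roughly uniform over random null sets", {
  set.seed(33)
  study <- tiny_study(n = 120, n_genes = 60, causal = 0, h2 = 0,
                      replicates = 1, seed = 19)
  plan <- permutation_plan(120, B = 199, seed = 5)
  s1 <- run_step1(study$genotypes, study$gene_map, study$phenotypes[[1]],
                  plan, tests = "CMC-1")
  sets <- make_random_sets(names(study$gene_map), n_sets = 200,
                           size_range = c(3, 10), seed = 3)
  res <- enrich_sets(s1[["CMC-1"]], sets, methods = "GSEA")
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(mean(res$p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("vsea_adjust standardizes every gene's permutation column", {
  set.seed(6)
  perm <- matrix(rchisq(50 * 10, df = 3) * rep(c(1, 10), each = 25), 50, 10)
  panel <- make_panel(rchisq(10, 3), perm)
  adj <- vsea_adjust(panel)
  expect_equal(unname(colMeans(adj$score_perm)), rep(0, 10),
               tolerance = 1e-12)
  expect_equal(unname(apply(adj$score_perm, 2,
                            function(v) sqrt(mean(v^2)))), rep(1, 10),
               tolerance = 1e-12)
  # direct standardization example: (5 - 2) / 1.5 = 2
  mu <- colMeans(panel$score_perm)
  sdv <- sqrt(colMeans(sweep(panel$score_perm, 2, mu)^2))
  expect_equal(unname(adj$score_obs),
               unname((panel$score_obs - mu) / sdv))

  # idempotence
  adj2 <- vsea_adjust(adj)
  expect_equal(adj2$score_obs, adj$score_obs, tolerance = 1e-10)
  expect_equal(adj2$score_perm, adj$score_perm, tolerance = 1e-10)

  # constant permutation scores -> flagged, adjusted to 0
  perm0 <- perm
  perm0[, 3] <- 1
  panel0 <- make_panel(rchisq(10, 3), perm0)
  adj0 <- vsea_adjust(panel0)
  expect_true(adj0$degenerate[[3]])
  expect_equal(unname(adj0$score_obs[3]), 0)

  small <- make_panel(1:3, matrix(1:27 / 10, 9, 3))
  expect_error(vsea_adjust(small), "fewer than 10")
})

test_that("VSEA equals GSEA when raw scores are already standardized", {
  set.seed(8)
  G <- 12
  perm <- apply(matrix(rnorm(40 * G), 40, G), 2, function(v) {
    (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  })
  panel <- make_panel(rnorm(G), perm)
  set <- c("g1", "g4", "g7")
  expect_equal(vsea_test(panel, set)$p, gsea_test(panel, set)$p)
  expect_equal(vsea_test(panel, set)$es, gsea_test(panel, set)$es)
})

test_that("standardization makes unequal-size genes comparable", {
  # two genes with the same true (standardized) association but 10x
  # different sizes: the raw cross-product statistic has a much wider null
  # spread for the big gene, so raw scores differ systematically; the
  # permutation-standardized scores should not
  set.seed(44)
  reps <- 30
  raw_small <- raw_big <- adj_small <- adj_big <- numeric(reps)
  spread_ratio <- numeric(reps)
  for (r in 1:reps) {
    n <- 150
    small <- matrix(rbinom(n * 2, 2, 0.05), n, 2)
    big <- matrix(rbinom(n * 20, 2, 0.05), n, 20)
    y <- 0.5 * scale(rowSums(small))[, 1] +
      0.5 * scale(rowSums(big))[, 1] + rnorm(n)
    g <- gm(cbind(small, big))
    gmap <- as_gene_map(list(small = 1:2, big = 3:22), g)
    plan <- permutation_plan(n, B = 99, seed = r)
    s1 <- run_step1(g, gmap, y, plan, tests = "WeightSum1")
    p <- s1[["WeightSum1"]]
    # treat the raw statistics as the gene scores
    p$score_obs <- p$stat_obs
    p$score_perm <- p$stat_perm
    a <- vsea_adjust(p)
    spread_ratio[r] <- stats::sd(p$stat_perm[, "big"]) /
      stats::sd(p$stat_perm[, "small"])
    raw_small[r] <- p$stat_obs[["small"]]
    raw_big[r] <- p$stat_obs[["big"]]
    adj_small[r] <- a$score_obs[["small"]]
    adj_big[r] <- a$score_obs[["big"]]
  }
  expect_gt(mean(spread_ratio), 2)  # the size-driven null heterogeneity
  expect_lt(abs(mean(adj_small) - mean(adj_big)),
            abs(mean(raw_small) - mean(raw_big)))
  # and the adjusted gap is small on the adjusted (z) scale
  expect_lt(abs(mean(adj_small) - mean(adj_big)), 1)
})

test_that("enrichment p is invariant to relabeling and monotone rescaling", {
  set.seed(13)
  perm <- matrix(rchisq(60 * 15, 2), 60, 15)
  obs <- rchisq(15, 2) + c(rep(3, 3), rep(0, 12))
  panel <- make_panel(obs, perm)
  set <- c("g1", "g2", "g3")
  p0 <- gsea_test(panel, set, exponent = 0)$p

  # relabel genes consistently
  relab <- paste0("h", 15:1)
  panel2 <- make_panel(obs, perm, genes = relab)
  expect_equal(gsea_test(panel2, c("h15", "h14", "h13"), exponent = 0)$p, p0)

  # strictly monotone rescaling of all scores (exponent 0 ignores weights):
  # apply to the score scale via a monotone transform of the statistics
  panel3 <- make_panel(obs * 7 + 1, perm * 7 + 1)
  expect_equal(gsea_test(panel3, set, exponent = 0)$p, p0)
})

test_that("gene-resampling null gives a usable alternative p", {
  set.seed(3)
  perm <- matrix(rchisq(30 * 20, 2), 30, 20)
  panel <- make_panel(c(rep(8, 4), rchisq(16, 2)), perm)
  r <- gsea_test(panel, paste0("g", 1:4), null = "geneset", n_null = 199,
                 seed = 7)
  expect_lte(r$p, 0.1)
  r2 <- gsea_test(panel, paste0("g", 1:4), null = "geneset", n_null = 199,
                  seed = 7)
  expect_identical(r, r2)
})
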