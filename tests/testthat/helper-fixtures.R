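# Shared fixtures and independent oracles.

# small genotype matrix from a plain dosage matrix
gm <- function(dosages, ...) genotype_matrix(as.matrix(dosages), ...)

# brute-force joint-F regression oracle: normal equations solved by
# hand-rolled Gaussian elimination, independent of the package's QR path.
gauss_solve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (k in seq_len(n)) {
    piv <- which.max(abs(M[k:n, k])) + k - 1
    if (abs(M[piv, k]) < 1e-12) stop("singular system")
    if (piv != k) M[c(k, piv), ] <- M[c(piv, k), ]
    M[k, ] <- M[k, ] / M[k, k]
    for (i in seq_len(n)[-k]) M[i, ] <- M[i, ] - M[i, k] * M[k, ]
  }
  M[, n + 1]
}

brute_joint_f_p <- function(y, X) {
  Xf <- cbind(1, as.matrix(X))
  beta <- gauss_solve(crossprod(Xf), crossprod(Xf, y))
  rss <- sum((y - Xf %*% beta)^2)
  tss <- sum((y - mean(y))^2)
  k <- ncol(Xf) - 1
  df2 <- length(y) - ncol(Xf)
  f <- ((tss - rss) / k) / (rss / df2)
  stats::pf(f, k, df2, lower.tail = FALSE)
}

# brute-force minor allele frequency by tallying alleles one by one
brute_maf <- function(dosages) {
  apply(as.matrix(dosages), 2, function(col) {
    col <- col[!is.na(col)]
    alt <- 0
    for (d in col) alt <- alt + d
    f <- alt / (2 * length(col))
    min(f, 1 - f)
  })
}

# brute-force running-sum ES materializing the whole running sum
brute_es <- function(scores, members, exponent) {
  genes <- names(scores)
  ord <- order(-scores, genes)
  genes <- genes[ord]
  scores <- scores[ord]
  run <- numeric(length(scores))
  acc <- 0
  hits <- genes %in% members
  w <- abs(scores[hits])^exponent
  tot <- sum(w)
  for (i in seq_along(scores)) {
    if (hits[i]) {
      acc <- acc + (if (tot > 0) abs(scores[i])^exponent / tot
                    else 1 / sum(hits))
    } else {
      acc <- acc - 1 / (length(scores) - sum(hits))
    }
    run[i] <- acc
  }
  run[which.max(abs(run))]
}

# tiny deterministic study used across tests
tiny_study <- function(n = 120, n_genes = 25, causal = 3, h2 = 0.4,
                       replicates = 2, seed = 42, ...) {
  simulate_study(simulation_config(
    n_individuals = n, n_genes = n_genes,
    gene_size_range = c(2, 12),
    causal_genes = causal, effect_sizes = 1.5,
    heritability = h2, n_replicates = replicates, seed = seed, ...
  ))
}
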