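test_that("dimension reduction removes the maximal low-count row set", {
  M <- matrix(c(1, 4, 95), 3, 1)
  red <- reduce_dimensions(M, 0.01)
  expect_equal(red$removed_rows, 1L)
  expect_equal(red$kept_rows, c(2L, 3L))

  M2 <- matrix(c(0, 0, 50, 50), 4, 1)
  red2 <- reduce_dimensions(M2, 0.01)
  expect_equal(red2$removed_rows, c(1L, 2L))

  expect_error(reduce_dimensions(matrix(0, 2, 1), 0.5), "degenerate")

  # brute-force maximality oracle on the candidate (smallest) rows
  set.seed(31)
  M3 <- matrix(rpois(96 * 20, 5), 96, 20)
  M3[sample(96, 8), ] <- rpois(8 * 20, 0.05)
  red3 <- reduce_dimensions(M3, 0.01)
  totals <- rowSums(M3)
  cand <- order(totals)[1:10]
  budget <- 0.01 * sum(totals)
  best <- 0L
  for (size in 1:10) {
    combs <- utils::combn(cand, size)
    sums <- colSums(matrix(totals[combs], nrow = size))
    if (any(sums <= budget)) best <- size
  }
  expect_equal(length(red3$removed_rows), best)
  expect_lte(sum(totals[red3$removed_rows]), budget)
})

test_that("bootstrap preserves per-genome totals exactly", {
  set.seed(32)
  M <- matrix(rpois(30, 40), 6, 5)
  for (r in 1:20) {
    B <- bootstrap_catalog(M)
    expect_identical(colSums(B), colSums(M))
    expect_true(all(B >= 0))
  }

  # degenerate column: all mass on one type is reproduced exactly
  M1 <- matrix(c(0, 7, 0), 3, 1)
  expect_identical(bootstrap_catalog(M1), M1)

  expect_error(bootstrap_catalog(matrix(0, 3, 1)), "zero-total")

  # multinomial expectation: cell-wise mean over replicates ~ input
  M2 <- matrix(c(10, 30, 60, 25, 50, 25), 3, 2)
  set.seed(33)
  acc <- Reduce(`+`, lapply(1:1000, function(i) bootstrap_catalog(M2)))
  expect_equal(acc / 1000, M2, tolerance = 0.05)
})

test_that("cosine similarity matches its defining formula and endpoints", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0, 2), c(0, 3, 0)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(c(1, 1), c(1, 1, 1)), "length")
})

test_that("consensus clustering recovers permuted and perturbed prototypes", {
  set.seed(34)
  proto <- random_signature(build_alphabet("SBS6"), 0.5, n = 3)

  # identical signatures up to column permutation: perfect clusters
  S_P <- lapply(1:5, function(i) proto[, sample(3)])
  cl <- cluster_signatures(S_P, NULL, 3)
  sim <- sapply(1:3, function(j) max(sapply(1:3, function(k)
    cosine(cl$centroids[, j], proto[, k]))))
  expect_equal(unname(sim), rep(1, 3), tolerance = 1e-12)
  sil <- silhouette_widths(do.call(cbind, S_P),
                           as.integer(t(cl$memberships)))
  expect_equal(sil$overall, 1, tolerance = 1e-9)

  # two hand-built iterations with permuted columns: matching recovers it
  S2 <- list(proto, proto[, c(2, 3, 1)])
  cl2 <- cluster_signatures(S2, NULL, 3)
  expect_equal(cl2$memberships[2, ], cl2$memberships[1, c(2, 3, 1)])

  # perturbed copies of three prototypes: centroids stay close
  S3 <- lapply(1:10, function(i) {
    Q <- proto + matrix(runif(18, 0, 0.02), 6, 3)
    sweep(Q, 2, colSums(Q), "/")[, sample(3)]
  })
  cl3 <- cluster_signatures(S3, NULL, 3)
  sim3 <- sapply(1:3, function(j) max(sapply(1:3, function(k)
    cosine(cl3$centroids[, j], proto[, k]))))
  expect_true(all(sim3 > 0.99))
})

test_that("silhouette widths match the textbook formula on a 6-point instance", {
  pts <- cbind(c(1, 0.1, 0), c(1, 0.2, 0.1), c(0.9, 0.1, 0.2),
               c(0, 0.1, 1), c(0.1, 0, 0.9), c(0.2, 0.1, 1))
  labels <- c(1L, 1L, 1L, 2L, 2L, 2L)
  got <- silhouette_widths(pts, labels)

  D <- outer(1:6, 1:6, Vectorize(function(i, j) 1 - cosine(pts[, i], pts[, j])))
  s <- numeric(6)
  for (i in 1:6) {
    own <- setdiff(which(labels == labels[i]), i)
    a <- mean(D[i, own])
    b <- min(sapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl])))
    s[i] <- (b - a) / max(a, b)
  }
  expect_equal(unname(got$widths), s, tolerance = 1e-12)
  expect_equal(got$overall, mean(s), tolerance = 1e-12)
  expect_equal(unname(got$per_cluster),
               unname(tapply(s, labels, mean)), tolerance = 1e-12)

  # indistinguishable clusters: a ~ b, silhouette ~ 0
  same <- cbind(pts[, 1], pts[, 1], pts[, 1], pts[, 1])
  expect_equal(silhouette_widths(same, c(1L, 2L, 1L, 2L))$overall, 0)

  expect_error(silhouette_widths(pts, rep(1L, 6)), "2 clusters")
  expect_error(silhouette_widths(pts[, 1:2], 1:2), "singleton")
})

test_that("noiseless well-separated signatures are recovered end to end", {
  set.seed(36)
  # block-structured signatures (pairwise cosine < 0.3), 50 genomes
  fx <- make_exact_factorization(K = 24L, N = 4L, G = 50L, seed = 36)
  E <- matrix(round(runif(4 * 50, 100, 2000)), 4, 50)
  M <- simulate_catalogs(fx$P, E, noise_model = "none", seed = 37)
  cfg <- decipher_config(N = 4, I = 12, seed = 38,
                         nmf = nmf_config(conv_window = 2000, max_iter = 50000))
  res <- decipher_signatures(M, cfg)
  m <- match_signatures(res$P_bar, fx$P)
  expect_true(all(m$pairing$cosine >= 0.99))
  expect_gte(res$avg_silhouette, 0.95)
  # exposures recovered: normalized error small
  ee <- exposure_error(res$E_bar, E, m)
  expect_lt(mean(ee$frobenius_sig_norm), 0.05)
  # P_bar columns sum to one even after zero-row expansion
  expect_equal(unname(colSums(res$P_bar)), rep(1, 4), tolerance = 1e-8)
  expect_true(all(res$P_bar[res$removed_rows, ] == 0))
})

test_that("deciphering is deterministic for a fixed seed", {
  set.seed(39)
  fx <- make_exact_factorization(K = 10L, N = 2L, G = 12L, seed = 39)
  M <- round(fx$M)
  M[M < 0] <- 0
  cfg <- decipher_config(N = 2, I = 5, seed = 40,
                         nmf = nmf_config(conv_window = 500, max_iter = 20000))
  r1 <- decipher_signatures(M, cfg)
  r2 <- decipher_signatures(M, cfg)
  expect_identical(r1$P_bar, r2$P_bar)
  expect_identical(r1$E_bar, r2$E_bar)
  expect_identical(r1$avg_silhouette, r2$avg_silhouette)
})

test_that("N = 1 consensus is the normalised mean with silhouette 1", {
  set.seed(41)
  M <- matrix(rpois(40, 30), 8, 5)
  cfg <- decipher_config(N = 1, I = 4, seed = 42,
                         nmf = nmf_config(conv_window = 500, max_iter = 20000))
  res <- decipher_signatures(M, cfg)
  expect_equal(res$avg_silhouette, 1)
  expect_equal(unname(colSums(res$P_bar)), 1, tolerance = 1e-8)
  # rank-1 consensus is proportional to the (kept) row profile
  prof <- rowSums(M) / sum(M)
  expect_gt(cosine(res$P_bar[, 1], prof), 0.99)

  expect_error(
    decipher_signatures(M, decipher_config(N = 6, I = 2, seed = 1)),
    "exceeds")
})

test_that("auto-I adds batches until the consensus stabilises", {
  fx <- make_exact_factorization(K = 10L, N = 2L, G = 10L, seed = 43)
  M <- round(fx$M)
  cfg <- decipher_config(N = 2, I = "auto", auto_I_batch = 5L,
                         auto_I_tol = 1e-3, max_I = 20L, seed = 44,
                         nmf = nmf_config(conv_window = 500, max_iter = 20000))
  res <- decipher_signatures(M, cfg)
  expect_gte(res$I_used, 10L)   # at least two batches are always compared
  expect_lte(res$I_used, 20L)
})
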