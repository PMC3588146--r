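test_that("random signatures are probability densities over the alphabet", {
  ab <- build_alphabet("SBS96")
  P <- random_signature(ab, concentration = 0.5, n = 20, seed = 1)
  expect_true(all(P >= 0))
  expect_equal(unname(colSums(P)), rep(1, 20), tolerance = 1e-12)

  # large concentration approaches the uniform density
  flat <- random_signature(ab, concentration = 1e6, seed = 2)
  expect_equal(as.vector(flat), rep(1 / 96, 96), tolerance = 0.01)

  expect_error(random_signature(ab, concentration = 0), "> 0")
})

test_that("mean pairwise cosine of Dirichlet(1) draws matches the Monte-Carlo oracle", {
  # oracle: 20,000 independent rgamma-normalised pairs at K = 96 give a
  # mean pairwise cosine of 0.509 (frozen; SE ~ 4e-4)
  ab <- build_alphabet("SBS96")
  set.seed(77)
  sims <- replicate(1000, {
    p <- random_signature(ab, concentration = 1, n = 2)
    cosine(p[, 1], p[, 2])
  })
  expect_equal(mean(sims), 0.509, tolerance = 0.02)
})

test_that("similarity-constrained pairs land in the target range", {
  ab <- build_alphabet("SBS96")
  base <- random_signature(ab, 0.5, seed = 4)[, 1]
  expect_identical(signature_pair_with_similarity(base, c(1, 1)), base)

  hi <- signature_pair_with_similarity(base, c(0.9, 1.0), seed = 5)
  s_hi <- cosine_similarity(base, hi)
  expect_gte(s_hi, 0.9)
  expect_lte(s_hi, 1.0)
  expect_equal(sum(hi), 1, tolerance = 1e-12)

  mid <- signature_pair_with_similarity(base, c(0.5, 0.6), seed = 6)
  s_mid <- cosine_similarity(base, mid)
  expect_gte(s_mid, 0.5)
  expect_lte(s_mid, 0.6)
})

test_that("exposures respect totals, bounds and constraint models", {
  ab <- build_alphabet("SBS96")
  spec <- simulation_spec(N = 7, G = 100, alphabet = ab, seed = 8)
  E <- simulate_exposures(spec)
  tot <- colSums(E)
  expect_true(all(tot >= 500 & tot <= 50000))
  expect_true(all(E >= 0))
  expect_true(all(E == round(E)))

  specf <- simulation_spec(N = 7, G = 40, alphabet = ab,
                           exposure_model = "fixed_fraction_per_genome",
                           fixed_fraction = 0.10, seed = 9)
  Ef <- simulate_exposures(specf)
  expect_equal(unname(Ef[1, ]), unname(round(0.10 * colSums(Ef))))

  speco <- simulation_spec(N = 7, G = 40, alphabet = ab,
                           exposure_model = "fixed_fraction_overall",
                           fixed_fraction = 0.10, seed = 10)
  Eo <- simulate_exposures(speco)
  expect_equal(sum(Eo[1, ]) / sum(Eo), 0.10, tolerance = 0.001)

  expect_error(simulation_spec(N = 2, G = 5,
                               exposure_model = "fixed_fraction_per_genome",
                               fixed_fraction = 1.5), "fixed_fraction")

  # uniform split: each signature's long-run mean share is 1/N
  spec2 <- simulation_spec(N = 2, G = 400, alphabet = ab, seed = 11)
  E2 <- simulate_exposures(spec2)
  share <- E2[1, ] / colSums(E2)
  expect_equal(mean(share), 0.5, tolerance = 0.05)
})

test_that("catalog realisation conserves counts and mean structure", {
  ab <- build_alphabet("SBS6")
  set.seed(12)
  P <- random_signature(ab, 0.5, n = 3)
  E <- matrix(c(1000L, 1500L, 750L), nrow = 3, ncol = 1)

  M0 <- simulate_catalogs(P, E, noise_model = "none", seed = 13)
  expect_equal(unname(colSums(M0)), unname(colSums(E)))

  # the worked single-genome example: 3,250 process mutations plus
  # ~2% white noise = 65 extra mutations, 3,315 in total
  Mw <- simulate_catalogs(P, E, noise_model = "additive_white",
                          white_noise_fraction = 0.02, seed = 14)
  expect_equal(sum(Mw), 3315L)

  # Poisson resampling: cell means equal the linear-superposition
  # expectation P %*% E over replicates
  set.seed(15)
  reps <- sapply(seq_len(1000), function(i) {
    as.vector(simulate_catalogs(P, E, noise_model = "poisson_resample"))
  })
  mu <- as.vector(P %*% E)
  expect_equal(rowMeans(reps), mu, tolerance = 0.05)
})

test_that("simulation truth is seed-reproducible and internally consistent", {
  spec <- simulation_spec(N = 4, G = 10, seed = 16)
  t1 <- simulate_truth(spec)
  t2 <- simulate_truth(spec)
  expect_identical(t1$M$counts, t2$M$counts)
  expect_identical(t1$P_true, t2$P_true)
  t3 <- simulate_truth(spec, seed = 17)
  expect_false(identical(t1$M$counts, t3$M$counts))
  expect_equal(unname(colSums(t1$P_true)), rep(1, 4), tolerance = 1e-12)

  # similarity constraints are honoured in the generated truth
  spec_sim <- simulation_spec(
    N = 4, G = 10,
    similarity_constraints = list(list(pair = c(3, 4), range = c(0.9, 1))),
    seed = 18)
  tt <- simulate_truth(spec_sim)
  expect_gte(cosine(tt$P_true[, 3], tt$P_true[, 4]), 0.9)
})
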