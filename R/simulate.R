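#' Specify a catalog simulation
#'
#' Bundles the parameters of the catalog simulator: N signatures are drawn
#' stochastically (symmetric Dirichlet), exposures split per-genome mutation
#' totals across signatures, and catalogs are realised by multinomial
#' sampling of each signature's contribution, with optional noise.
#'
#' @param N Number of signatures (processes).
#' @param G Number of genomes (samples).
#' @param alphabet A `sig_alphabet` (default SBS96).
#' @param min_mutations,max_mutations Range of per-genome mutation totals;
#'   totals are drawn log-uniformly on this interval (default 500-50,000,
#'   the span observed across many human cancer genomes).
#' @param concentration Symmetric Dirichlet concentration for random
#'   signatures; the default 0.5 produces peaked, signature-like profiles.
#' @param similarity_constraints Optional list of constraints
#'   `list(pair = c(i, j), range = c(lo, hi))`: signature `j` is constructed
#'   so that its cosine similarity to signature `i` falls in `range`.
#' @param exposure_model One of `"uniform_random"` (proportions uniform on
#'   the simplex per genome), `"fixed_fraction_per_genome"` (signature 1
#'   contributes `fixed_fraction` of every genome's mutations), or
#'   `"fixed_fraction_overall"` (signature 1 contributes `fixed_fraction` of
#'   all mutations in the set, with per-genome shares free).
#' @param fixed_fraction Fraction in `[0, 1]` for the fixed-fraction models.
#' @param noise_model `"poisson_resample"` (each catalog cell is re-drawn
#'   Poisson with mean equal to its noiseless value; the default),
#'   `"additive_white"` (extra uniformly-typed mutations totalling
#'   `white_noise_fraction` of each genome's mutations), or `"none"`.
#' @param white_noise_fraction Proportion of extra white-noise mutations for
#'   `"additive_white"`.
#' @param seed Optional integer seed.
#' @return A `sig_simspec` list.
#' @export
simulation_spec <- function(N, G, alphabet = build_alphabet("SBS96"),
                            min_mutations = 500L, max_mutations = 50000L,
                            concentration = 0.5,
                            similarity_constraints = NULL,
                            exposure_model = c("uniform_random",
                                               "fixed_fraction_per_genome",
                                               "fixed_fraction_overall"),
                            fixed_fraction = NULL,
                            noise_model = c("poisson_resample",
                                            "additive_white", "none"),
                            white_noise_fraction = 0.02,
                            seed = NULL) {
  exposure_model <- match.arg(exposure_model)
  noise_model <- match.arg(noise_model)
  stopifnot(N >= 1, G >= 1, inherits(alphabet, "sig_alphabet"),
            min_mutations >= 1, max_mutations >= min_mutations,
            concentration > 0,
            white_noise_fraction >= 0, white_noise_fraction <= 1)
  if (startsWith(exposure_model, "fixed_fraction")) {
    if (is.null(fixed_fraction) || fixed_fraction < 0 || fixed_fraction > 1) {
      stop("fixed-fraction exposure models need fixed_fraction in [0, 1]")
    }
  }
  for (sc in similarity_constraints) {
    stopifnot(length(sc$pair) == 2L, all(sc$range >= 0), all(sc$range <= 1),
              sc$range[1] <= sc$range[2])
  }
  structure(list(
    N = as.integer(N), G = as.integer(G), alphabet = alphabet,
    min_mutations = min_mutations, max_mutations = max_mutations,
    concentration = concentration,
    similarity_constraints = similarity_constraints,
    exposure_model = exposure_model, fixed_fraction = fixed_fraction,
    noise_model = noise_model, white_noise_fraction = white_noise_fraction,
    seed = seed
  ), class = "sig_simspec")
}

#' Draw random mutational signatures
#'
#' Signatures are drawn from a symmetric Dirichlet distribution over the K
#' mutation types, so every draw is a nonnegative vector summing to 1 (a
#' discrete probability density over the alphabet). Small concentrations
#' give peaked profiles; as the concentration grows the draw approaches the
#' uniform distribution 1/K.
#'
#' @param alphabet A `sig_alphabet`.
#' @param concentration Positive Dirichlet concentration parameter.
#' @param n Number of signatures to draw.
#' @param seed Optional integer seed.
#' @return A K x n matrix (rows named by type labels, columns `S1..Sn`).
#' @export
random_signature <- function(alphabet, concentration = 0.5, n = 1L,
                             seed = NULL) {
  stopifnot(inherits(alphabet, "sig_alphabet"))
  if (concentration <= 0) stop("concentration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  K <- alphabet$K
  P <- matrix(stats::rgamma(K * n, shape = concentration, rate = 1),
              nrow = K, ncol = n)
  # guard against an all-zero column at tiny concentrations
  zero <- colSums(P) == 0
  if (any(zero)) P[, zero] <- 1 / K
  P <- sweep(P, 2, colSums(P), "/")
  dimnames(P) <- list(alphabet$labels, paste0("S", seq_len(n)))
  P
}

#' Construct a signature with a prescribed similarity to a base signature
#'
#' Convexly mixes an independent random signature with `base` and tunes the
#' mixing weight by bisection until the cosine similarity to `base` falls in
#' `target_range`. Used to build the "extremely similar signatures"
#' scenarios of the power analyses.
#'
#' @param base A signature vector (nonnegative, sums to 1).
#' @param target_range Numeric interval within `[0, 1]`.
#' @param alphabet Optional `sig_alphabet` (defaults to the length of
#'   `base`).
#' @param concentration Dirichlet concentration of the random partner.
#' @param max_attempts Random partners to try before giving up.
#' @param seed Optional integer seed.
#' @return A signature vector with `cosine_similarity(base, result)` in
#'   `target_range`.
#' @export
signature_pair_with_similarity <- function(base, target_range,
                                           alphabet = NULL,
                                           concentration = 0.5,
                                           max_attempts = 50L,
                                           seed = NULL) {
  stopifnot(length(target_range) == 2L, target_range[1] <= target_range[2],
            target_range[1] >= 0, target_range[2] <= 1)
  if (!is.null(seed)) set.seed(seed)
  base <- base / sum(base)
  if (target_range[1] >= 1) return(base)
  if (is.null(alphabet)) {
    alphabet <- structure(list(scheme = "custom",
                               labels = names(base) %||%
                                 paste0("T", seq_along(base)),
                               K = length(base)),
                          class = "sig_alphabet")
  }
  achieved <- NA_real_
  for (attempt in seq_len(max_attempts)) {
    other <- as.vector(random_signature(alphabet, concentration))
    mix_sim <- function(w) {
      v <- (1 - w) * other + w * base
      cosine_similarity(v, base)
    }
    lo <- 0; hi <- 1
    s_lo <- mix_sim(0)
    achieved <- s_lo
    if (s_lo > target_range[2]) next  # partner already too similar
    for (it in seq_len(200L)) {
      mid <- (lo + hi) / 2
      s <- mix_sim(mid)
      achieved <- s
      if (s >= target_range[1] && s <= target_range[2]) {
        v <- (1 - mid) * other + mid * base
        v <- v / sum(v)
        names(v) <- names(base)
        return(v)
      }
      if (s < target_range[1]) lo <- mid else hi <- mid
    }
  }
  stop(sprintf(
    "could not reach target similarity [%g, %g]; best achieved %g",
    target_range[1], target_range[2], achieved))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# integer split of `total` proportional to weights, preserving the total
# exactly (largest-remainder rounding; ties broken by index order)
largest_remainder <- function(weights, total) {
  if (total == 0 || sum(weights) == 0) return(integer(length(weights)))
  x <- weights / sum(weights) * total
  f <- floor(x)
  rem <- total - sum(f)
  if (rem > 0) {
    idx <- order(x - f, decreasing = TRUE)[seq_len(rem)]
    f[idx] <- f[idx] + 1
  }
  as.integer(f)
}

#' Simulate an exposure matrix
#'
#' Per genome, a total mutation count is drawn log-uniformly from
#' `[min_mutations, max_mutations]` and split across the N signatures
#' according to the spec's exposure model. Integer splitting uses
#' largest-remainder rounding so every column total is preserved exactly.
#'
#' @param spec A `sig_simspec`.
#' @param seed Optional integer seed.
#' @return An N x G integer matrix of exposures (rows `S1..SN`).
#' @export
simulate_exposures <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sig_simspec"))
  if (!is.null(seed)) set.seed(seed)
  N <- spec$N; G <- spec$G
  totals <- round(exp(stats::runif(G, log(spec$min_mutations),
                                   log(spec$max_mutations))))
  E <- matrix(0L, nrow = N, ncol = G,
              dimnames = list(paste0("S", seq_len(N)),
                              paste0("G", seq_len(G))))
  if (spec$exposure_model == "uniform_random") {
    for (g in seq_len(G)) {
      w <- stats::rexp(N)  # normalised Exp(1) is uniform on the simplex
      E[, g] <- largest_remainder(w, totals[g])
    }
  } else if (spec$exposure_model == "fixed_fraction_per_genome") {
    f <- spec$fixed_fraction
    for (g in seq_len(G)) {
      e1 <- round(f * totals[g])
      if (N == 1L) {
        E[, g] <- totals[g]
      } else {
        w <- stats::rexp(N - 1L)
        E[, g] <- c(e1, largest_remainder(w, totals[g] - e1))
      }
    }
  } else { # fixed_fraction_overall
    f <- spec$fixed_fraction
    target1 <- round(f * sum(totals))
    # random per-genome weights for signature 1, capped by column totals
    raw <- stats::runif(G) * totals
    e1 <- largest_remainder(raw, target1)
    over <- e1 > totals
    while (any(over)) {
      excess <- sum(e1[over] - totals[over])
      e1[over] <- totals[over]
      room <- totals - e1
      if (sum(room) == 0 || excess == 0) break
      e1 <- e1 + largest_remainder(room, min(excess, sum(room)))
      over <- e1 > totals
    }
    for (g in seq_len(G)) {
      if (N == 1L) {
        E[, g] <- totals[g]
      } else {
        w <- stats::rexp(N - 1L)
        E[, g] <- c(e1[g], largest_remainder(w, totals[g] - e1[g]))
      }
    }
  }
  storage.mode(E) <- "integer"
  E
}

#' Realise catalogs from true signatures and exposures
#'
#' For every genome g and signature n, the `E_true[n, g]` mutations are
#' assigned to mutation types by a multinomial draw from column n of
#' `P_true`, so that with noise disabled `E[M] = P_true %*% E_true` and
#' column sums equal the exposure column sums exactly. Poisson noise
#' re-draws every catalog cell with its noiseless value as the mean;
#' additive white noise appends uniformly-typed extra mutations.
#'
#' @param P_true K x N signature matrix (columns sum to 1).
#' @param E_true N x G exposure matrix (nonnegative integers).
#' @param noise_model,white_noise_fraction See [simulation_spec()].
#' @param alphabet Optional `sig_alphabet` for the resulting catalog.
#' @param seed Optional integer seed.
#' @return A `sig_catalog` (or plain matrix when no alphabet matches K).
#' @export
simulate_catalogs <- function(P_true, E_true,
                              noise_model = c("poisson_resample",
                                              "additive_white", "none"),
                              white_noise_fraction = 0.02,
                              alphabet = NULL, seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (!is.null(seed)) set.seed(seed)
  P_true <- as.matrix(P_true); E_true <- as.matrix(E_true)
  if (ncol(P_true) != nrow(E_true)) stop("P_true and E_true are incompatible")
  K <- nrow(P_true); G <- ncol(E_true); N <- ncol(P_true)
  M <- matrix(0L, nrow = K, ncol = G)
  for (g in seq_len(G)) {
    col <- numeric(K)
    for (n in seq_len(N)) {
      e <- E_true[n, g]
      if (e > 0) col <- col + stats::rmultinom(1, e, P_true[, n])[, 1]
    }
    M[, g] <- col
  }
  if (noise_model == "poisson_resample") {
    M <- matrix(stats::rpois(K * G, lambda = as.vector(M)), nrow = K)
  } else if (noise_model == "additive_white") {
    extra <- round(white_noise_fraction * colSums(M))
    for (g in seq_len(G)) {
      if (extra[g] > 0) {
        M[, g] <- M[, g] + stats::rmultinom(1, extra[g], rep(1 / K, K))[, 1]
      }
    }
  }
  storage.mode(M) <- "integer"
  if (is.null(alphabet) || alphabet$K != K) {
    dimnames(M) <- list(rownames(P_true), paste0("G", seq_len(G)))
    return(M)
  }
  new_catalog(M, alphabet, paste0("G", seq_len(G)))
}

#' Simulate a full catalog set with known truth
#'
#' Draws the true signatures (applying any similarity constraints), the
#' exposures and the noisy catalogs, returning everything needed to score a
#' deciphering run against the generating truth.
#'
#' @param spec A `sig_simspec`.
#' @param seed Optional integer seed (overrides `spec$seed`).
#' @return A `sig_simulation` list: `P_true` (K x N), `E_true` (N x G),
#'   `M` (a `sig_catalog`), and `seed`.
#' @export
simulate_truth <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "sig_simspec"))
  if (!is.null(seed)) set.seed(seed)
  P <- random_signature(spec$alphabet, spec$concentration, n = spec$N)
  for (sc in spec$similarity_constraints) {
    i <- sc$pair[1]; j <- sc$pair[2]
    P[, j] <- signature_pair_with_similarity(
      P[, i], sc$range, alphabet = spec$alphabet,
      concentration = spec$concentration)
  }
  E <- simulate_exposures(spec)
  M <- simulate_catalogs(P, E, noise_model = spec$noise_model,
                         white_noise_fraction = spec$white_noise_fraction,
                         alphabet = spec$alphabet)
  structure(list(P_true = P, E_true = E, M = M, seed = seed),
            class = "sig_simulation")
}
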