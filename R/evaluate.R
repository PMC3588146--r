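#' Match extracted signatures to true signatures
#'
#' Optimal one-to-one assignment (Hungarian algorithm) maximising the total
#' cosine similarity between extracted and true signature columns. Accuracy
#' of 1.00 for a pair means the extracted signature is exactly the
#' generating one; extracted signatures with cosine similarity above
#' `accurate_min` to their matched truth are flagged as accurately
#' deciphered.
#'
#' @param P_extracted,P_true Signature matrices over the same alphabet
#'   (equal row counts); column counts may differ, in which case
#'   `min(N_extracted, N_true)` pairs are formed.
#' @param accurate_min Cosine threshold for the `accurate` flag
#'   (default 0.95).
#' @return A `sig_match` list: `pairing` data frame (extracted, true,
#'   cosine, accurate) and `mean_cosine`.
#' @export
match_signatures <- function(P_extracted, P_true, accurate_min = 0.95) {
  P_extracted <- as.matrix(P_extracted)
  P_true <- as.matrix(P_true)
  if (nrow(P_extracted) != nrow(P_true)) {
    stop("signature matrices are defined over different alphabets ",
         "(row counts ", nrow(P_extracted), " vs ", nrow(P_true), ")")
  }
  sim <- cosine_sim_matrix(P_extracted, P_true)
  assign <- solve_assignment(sim, maximize = TRUE)
  keep <- which(assign > 0L)
  pairing <- data.frame(
    extracted = keep,
    true = assign[keep],
    cosine = sim[cbind(keep, assign[keep])]
  )
  pairing <- pairing[order(pairing$extracted), , drop = FALSE]
  pairing$accurate <- pairing$cosine > accurate_min
  structure(list(pairing = pairing, mean_cosine = mean(pairing$cosine)),
            class = "sig_match")
}

#' Exposure (contribution) errors per matched signature
#'
#' For each matched signature pair, two error measures over genomes:
#'
#' * Normalized Frobenius error: `sqrt(sum_g (e_g - ehat_g)^2)` divided by a
#'   mutation total -- the signature's total true contribution
#'   (`frobenius_sig_norm`) and, alternatively, the total mutations in the
#'   catalogs (`frobenius_catalog_norm`); both normalizations are emitted.
#' * SMAPE, the symmetric mean absolute percentage error:
#'   `mean_g 2|e - ehat| / (|e| + |ehat|)`, with 0/0 terms defined as 0.
#'
#' @param E_extracted,E_true Exposure matrices (N x G) over the same
#'   samples.
#' @param pairing A `sig_match` (or its `pairing` data frame).
#' @return A data frame with one row per pair: extracted, true,
#'   `frobenius_sig_norm`, `frobenius_catalog_norm`, `smape`.
#' @export
exposure_error <- function(E_extracted, E_true, pairing) {
  if (inherits(pairing, "sig_match")) pairing <- pairing$pairing
  E_extracted <- as.matrix(E_extracted)
  E_true <- as.matrix(E_true)
  if (ncol(E_extracted) != ncol(E_true)) {
    stop("exposure matrices have different sample counts")
  }
  catalog_total <- sum(E_true)
  out <- pairing[, c("extracted", "true")]
  out$frobenius_sig_norm <- NA_real_
  out$frobenius_catalog_norm <- NA_real_
  out$smape <- NA_real_
  for (r in seq_len(nrow(pairing))) {
    ehat <- E_extracted[pairing$extracted[r], ]
    e <- E_true[pairing$true[r], ]
    fe <- sqrt(sum((e - ehat)^2))
    sig_total <- sum(e)
    out$frobenius_sig_norm[r] <- if (sig_total > 0) fe / sig_total else 0
    out$frobenius_catalog_norm[r] <-
      if (catalog_total > 0) fe / catalog_total else 0
    denom <- abs(e) + abs(ehat)
    terms <- ifelse(denom == 0, 0, 2 * abs(e - ehat) / denom)
    out$smape[r] <- mean(terms)
  }
  out
}

#' Run a simulation scenario end to end, repeatedly
#'
#' For each replicate: simulate catalogs from known truth, decipher, match
#' the averaged signatures to the generating ones, and score signature
#' accuracy (cosine) and exposure errors. Means and SDs over replicates are
#' the error bars of the power analyses. With a single replicate the SDs
#' are reported as 0 by convention.
#'
#' @param spec A `sig_simspec`.
#' @param cfg A `sig_decipher_config`.
#' @param replicates Number of independent replicates (default 10; the full
#'   study convention of 100 is available but slow).
#' @param seed Master seed; replicate r uses `seed + r`.
#' @return A `sig_scenario` list: `per_replicate` data frame (replicate,
#'   mean_cosine, min_cosine, n_accurate, mean_smape,
#'   mean_frobenius_sig_norm, avg_silhouette), `mean_accuracy`,
#'   `sd_accuracy`, `mean_smape`, `sd_smape`, `replicates`.
#' @export
run_scenario <- function(spec, cfg, replicates = 10L, seed = 1L) {
  stopifnot(replicates >= 1)
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    truth <- simulate_truth(spec, seed = (seed + r) %% .Machine$integer.max)
    cfg_r <- cfg
    cfg_r$seed <- (seed + 100000L + r) %% .Machine$integer.max
    res <- decipher_signatures(truth$M, cfg_r)
    m <- match_signatures(res$P_bar, truth$P_true)
    ee <- exposure_error(res$E_bar, truth$E_true, m)
    rows[[r]] <- data.frame(
      replicate = r,
      mean_cosine = m$mean_cosine,
      min_cosine = min(m$pairing$cosine),
      n_accurate = sum(m$pairing$accurate),
      mean_smape = mean(ee$smape),
      mean_frobenius_sig_norm = mean(ee$frobenius_sig_norm),
      avg_silhouette = res$avg_silhouette
    )
  }
  per <- do.call(rbind, rows)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  structure(list(
    per_replicate = per,
    mean_accuracy = mean(per$mean_cosine),
    sd_accuracy = sd0(per$mean_cosine),
    mean_smape = mean(per$mean_smape),
    sd_smape = sd0(per$mean_smape),
    replicates = replicates
  ), class = "sig_scenario")
}
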