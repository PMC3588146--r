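#' Sweep the number of signatures N
#'
#' Runs the deciphering framework for each candidate N and records the two
#' model-selection curves: average silhouette width (reproducibility) and
#' squared Frobenius reconstruction error (fit). The plausible range of N is
#' 1 to min(K_dot, G) - 1. Each N uses an independent seed derived from the
#' master seed by a fixed offset, so sweeps are reproducible and
#' parallelizable.
#'
#' @param M A `sig_catalog` or count matrix.
#' @param N_range Integer vector of candidate N values (default the full
#'   feasible range; keep it short, each N is a full deciphering run).
#' @param cfg A `sig_decipher_config`; its `N` field is ignored.
#' @return A `sig_sweep` list: `per_N` data frame (N, avg_silhouette,
#'   reconstruction_error), `results` (the `sig_decipher_result` per N).
#' @export
sweep_N <- function(M, N_range = NULL, cfg) {
  stopifnot(inherits(cfg, "sig_decipher_config"))
  Mmat <- if (inherits(M, "sig_catalog")) M$counts else as.matrix(M)
  red <- reduce_dimensions(Mmat, cfg$removal_threshold)
  nmax <- min(nrow(red$M_dot), ncol(red$M_dot)) - 1L
  if (is.null(N_range)) N_range <- seq_len(nmax)
  N_range <- sort(unique(as.integer(N_range)))
  if (!length(N_range) || any(N_range < 1L) || any(N_range > nmax)) {
    stop("N_range must lie within [1, ", nmax, "]")
  }
  master <- cfg$seed %||% 1L
  results <- vector("list", length(N_range))
  per_N <- data.frame(N = N_range, avg_silhouette = NA_real_,
                      reconstruction_error = NA_real_)
  for (i in seq_along(N_range)) {
    n <- N_range[i]
    cfg_n <- cfg
    cfg_n$N <- n
    cfg_n$seed <- (master + 1000L * n) %% .Machine$integer.max
    res <- decipher_signatures(M, cfg_n)
    results[[i]] <- res
    per_N$avg_silhouette[i] <- res$avg_silhouette
    per_N$reconstruction_error[i] <- res$reconstruction_error
  }
  structure(list(per_N = per_N, results = results),
            class = "sig_sweep")
}

#' Select the number of signatures from sweep curves
#'
#' Codifies the visual rule "highly reproducible signatures and low overall
#' reconstruction error": the selected N is the smallest candidate whose
#' average silhouette width is at least `silhouette_min` and from which the
#' reconstruction-error curve has flattened onward -- every decrease between
#' consecutive larger N values, measured relative to the error at the
#' smallest swept N (the overall error scale), stays below
#' `error_flatten_ratio`. Adding signatures past the selected N no longer
#' buys reconstruction accuracy, and demanding flatness over the whole tail
#' keeps a brief spurious plateau in a still-falling curve from being
#' mistaken for the elbow. Returns `NA` when no N qualifies. The full
#' curves in `result$per_N` are always available for human review and
#' override.
#'
#' @param result A `sig_sweep`.
#' @param silhouette_min Reproducibility threshold (default 0.85).
#' @param error_flatten_ratio Flattening threshold (default 0.05).
#' @return The selected N (integer), or `NA_integer_`; the applied rule is
#'   attached as attribute `"rule"`.
#' @export
select_N <- function(result, silhouette_min = 0.85,
                     error_flatten_ratio = 0.05) {
  stopifnot(inherits(result, "sig_sweep"))
  df <- result$per_N[order(result$per_N$N), , drop = FALSE]
  if (!nrow(df)) stop("empty sweep")
  e0 <- df$reconstruction_error[1]
  n <- nrow(df)
  flat_step <- rep(TRUE, n)  # flat_step[i]: decrease from N_i to N_{i+1} small
  if (n > 1 && e0 > 0) {
    flat_step[-n] <-
      (df$reconstruction_error[-n] - df$reconstruction_error[-1]) / e0 <
      error_flatten_ratio
  }
  flat_onward <- rev(cumprod(rev(flat_step))) > 0
  ok <- df$avg_silhouette >= silhouette_min & flat_onward
  sel <- if (any(ok)) min(df$N[ok]) else NA_integer_
  attr(sel, "rule") <- sprintf(
    paste("smallest N with avg silhouette >= %g whose onward error",
          "decreases all stay < %g of the error at N = %d"),
    silhouette_min, error_flatten_ratio, df$N[1])
  sel
}
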