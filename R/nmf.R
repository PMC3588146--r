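#' NMF configuration
#'
#' Controls the multiplicative-update factorization. Convergence is declared
#' when the objective's relative decrease over the trailing `conv_window`
#' iterations falls below `conv_tol` ("no change" over the window), checked
#' every `check_every` iterations; otherwise the run stops at `max_iter`.
#'
#' @param max_iter Maximum iterations (default 1,000,000).
#' @param conv_window Trailing window, in iterations, over which "no change"
#'   is assessed (default 10,000).
#' @param conv_tol Relative objective-decrease threshold (default 1e-3: the
#'   objective must have decreased by less than 0.1 percent over the whole
#'   trailing window, about 1e-7 per iteration; beyond this point the
#'   factors move by far less than the bootstrap-to-bootstrap variation the
#'   consensus step averages over).
#' @param check_every Objective evaluation interval in iterations.
#' @param seed Optional integer seed for the random initialization.
#' @return A `sig_nmf_config` list.
#' @export
nmf_config <- function(max_iter = 1000000L, conv_window = 10000L,
                       conv_tol = 1e-3, check_every = 10L, seed = NULL) {
  stopifnot(conv_window < max_iter, conv_tol >= 0, check_every >= 1)
  structure(list(max_iter = as.integer(max_iter),
                 conv_window = as.integer(conv_window),
                 conv_tol = conv_tol,
                 check_every = as.integer(check_every),
                 seed = seed),
            class = "sig_nmf_config")
}

#' Nonnegative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative matrix `Mb` (typically a bootstrapped catalog)
#' as `Mb ~ P %*% E` with `N` signatures, minimising the squared Frobenius
#' norm by the classic multiplicative update rules
#' `E <- E * (P'Mb) / (P'PE)` and `P <- P * (Mb E') / (P E E')`.
#' `P` and `E` are initialised as random nonnegative matrices (i.i.d.
#' uniform on (0, 1], scaled by `mean(Mb) / N`); denominators are floored at
#' machine epsilon. On return `P` is column-normalized to sum 1 with `E`
#' rescaled so the product is unchanged.
#'
#' @param Mb Nonnegative numeric matrix (K x G) or `sig_catalog`.
#' @param N Factorization rank, `1 <= N <= min(K, G)`.
#' @param cfg A `sig_nmf_config`.
#' @param seed Optional integer seed (overrides `cfg$seed`).
#' @return A list with `P` (K x N, columns sum to 1), `E` (N x G),
#'   `trace` (data frame of iteration/objective checkpoints, non-increasing),
#'   `iterations` and `converged`.
#' @export
nmf_multiplicative <- function(Mb, N, cfg = nmf_config(), seed = cfg$seed) {
  if (inherits(Mb, "sig_catalog")) Mb <- Mb$counts
  Mb <- as.matrix(Mb)
  storage.mode(Mb) <- "double"
  if (any(Mb < 0)) stop("Mb must be nonnegative")
  if (all(Mb == 0)) stop("Mb is all zero")
  K <- nrow(Mb); G <- ncol(Mb)
  if (N < 1 || N > min(K, G)) {
    stop("N must lie in [1, min(K, G)] = [1, ", min(K, G), "]")
  }
  if (!is.null(seed)) set.seed(seed)
  scale <- mean(Mb) / N
  P0 <- matrix((1 - stats::runif(K * N)) * scale, K, N)  # uniform on (0, 1]
  E0 <- matrix((1 - stats::runif(N * G)) * scale, N, G)
  res <- .nmf_mu_cpp(Mb, P0, E0, cfg$max_iter, cfg$conv_window,
                     cfg$conv_tol, cfg$check_every)
  norm <- normalize_factorization(res$P, res$E)
  rownames(norm$P) <- rownames(Mb)
  colnames(norm$P) <- rownames(norm$E) <- paste0("S", seq_len(N))
  colnames(norm$E) <- colnames(Mb)
  list(P = norm$P, E = norm$E,
       trace = data.frame(iteration = res$trace_iter,
                          objective = res$trace_obj),
       iterations = res$iterations, converged = res$converged)
}

#' Squared Frobenius reconstruction error
#'
#' @param M Observed matrix (or `sig_catalog`).
#' @param P,E Factor matrices.
#' @return `sum((M - P %*% E)^2)`, a nonnegative scalar.
#' @export
frobenius_error <- function(M, P, E) {
  if (inherits(M, "sig_catalog")) M <- M$counts
  M <- as.matrix(M); P <- as.matrix(P); E <- as.matrix(E)
  if (ncol(P) != nrow(E) || nrow(P) != nrow(M) || ncol(E) != ncol(M)) {
    stop("incompatible shapes: M is ", nrow(M), "x", ncol(M),
         ", P is ", nrow(P), "x", ncol(P), ", E is ", nrow(E), "x", ncol(E))
  }
  sum((M - P %*% E)^2)
}

#' Normalize a factorization so signature columns sum to 1
#'
#' Divides each column of `P` by its sum and multiplies the corresponding
#' row of `E` by the same factor, leaving the product `P %*% E` unchanged.
#' Signatures then satisfy the probability normalization, and exposures are
#' expressed as mutation counts.
#'
#' @param P K x N nonnegative matrix with no all-zero column.
#' @param E N x G nonnegative matrix.
#' @return `list(P, E)` with `colSums(P) == 1`.
#' @export
normalize_factorization <- function(P, E) {
  P <- as.matrix(P); E <- as.matrix(E)
  if (ncol(P) != nrow(E)) stop("P and E are incompatible")
  s <- colSums(P)
  if (any(s == 0)) stop("all-zero signature column; cannot normalize")
  list(P = sweep(P, 2, s, "/"), E = E * s)
}
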