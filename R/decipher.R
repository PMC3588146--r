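#' Configuration for the deciphering framework
#'
#' @param N Number of signatures to extract.
#' @param I Number of bootstrap-NMF iterations, or `"auto"`: iterations are
#'   added in batches of `auto_I_batch` until the consensus signatures stop
#'   moving (maximum centroid shift, measured as 1 - cosine similarity
#'   between consecutive batch averages, below `auto_I_tol`), capped at
#'   `max_I`.
#' @param removal_threshold Dimension-reduction threshold: mutation types
#'   jointly accounting for at most this fraction of all mutations are
#'   removed before factorization (default 0.01).
#' @param nmf A `sig_nmf_config`.
#' @param auto_I_batch Batch size for `I = "auto"` (default 100).
#' @param auto_I_tol Centroid-shift tolerance for `I = "auto"`.
#' @param max_I Iteration cap (default 1000).
#' @param seed Optional integer seed governing the whole run.
#' @return A `sig_decipher_config` list.
#' @export
decipher_config <- function(N, I = "auto", removal_threshold = 0.01,
                            nmf = nmf_config(), auto_I_batch = 100L,
                            auto_I_tol = 1e-3, max_I = 1000L, seed = NULL) {
  stopifnot(N >= 1, removal_threshold >= 0, removal_threshold < 1,
            inherits(nmf, "sig_nmf_config"))
  if (!identical(I, "auto")) {
    stopifnot(is.numeric(I), I >= 1)
    I <- as.integer(I)
  }
  structure(list(N = as.integer(N), I = I,
                 removal_threshold = removal_threshold, nmf = nmf,
                 auto_I_batch = as.integer(auto_I_batch),
                 auto_I_tol = auto_I_tol, max_I = as.integer(max_I),
                 seed = seed),
            class = "sig_decipher_config")
}

#' Remove rarely mutated types before factorization
#'
#' Removes the largest possible set of mutation-type rows whose combined
#' count is at most `threshold` of the grand total (rows are considered in
#' ascending order of their totals, which maximises the number removed).
#' Rare types carry little signal but inflate bootstrap variance.
#'
#' @param M A `sig_catalog` or nonnegative matrix.
#' @param threshold Fraction in `[0, 1)` (default 0.01).
#' @return A `sig_reduced` list: `M_dot` (kept rows, original order),
#'   `kept_rows` and `removed_rows` (indices into the original row order).
#' @export
reduce_dimensions <- function(M, threshold = 0.01) {
  if (inherits(M, "sig_catalog")) M <- M$counts
  M <- as.matrix(M)
  stopifnot(all(M >= 0), threshold >= 0, threshold < 1)
  totals <- rowSums(M)
  grand <- sum(totals)
  ord <- order(totals)  # ascending; stable for ties
  removable <- cumsum(totals[ord]) <= threshold * grand
  removed <- sort(ord[removable])
  if (length(removed) == nrow(M)) {
    stop("all mutation-type rows fall under the removal threshold; ",
         "degenerate catalog")
  }
  kept <- setdiff(seq_len(nrow(M)), removed)
  structure(list(M_dot = M[kept, , drop = FALSE],
                 kept_rows = kept, removed_rows = removed),
            class = "sig_reduced")
}

#' Bootstrap a catalog matrix
#'
#' Monte Carlo bootstrap of each genome's catalog: column g is a multinomial
#' draw of its original total with type probabilities proportional to the
#' observed counts, so per-genome totals are preserved exactly.
#'
#' @param M_dot A `sig_reduced`, `sig_catalog`, or nonnegative matrix with
#'   strictly positive column totals.
#' @param seed Optional integer seed.
#' @return A matrix of the same shape with identical column sums.
#' @export
bootstrap_catalog <- function(M_dot, seed = NULL) {
  if (inherits(M_dot, "sig_reduced")) M_dot <- M_dot$M_dot
  if (inherits(M_dot, "sig_catalog")) M_dot <- M_dot$counts
  M_dot <- as.matrix(M_dot)
  if (!is.null(seed)) set.seed(seed)
  totals <- colSums(M_dot)
  if (any(totals <= 0)) stop("zero-total column; cannot bootstrap")
  out <- M_dot
  for (g in seq_len(ncol(M_dot))) {
    out[, g] <- stats::rmultinom(1, totals[g], M_dot[, g] / totals[g])[, 1]
  }
  out
}

#' Cosine similarity between nonnegative vectors
#'
#' `sim(A, B) = sum(A*B) / (sqrt(sum(A^2)) * sqrt(sum(B^2)))`; for
#' nonnegative vectors the range is `[0, 1]`, with 1 for identical profiles
#' and 0 for profiles with disjoint support.
#'
#' @param a,b Numeric vectors of equal length, neither all zero.
#' @return Scalar in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  sum(a * b) / (na * nb)
}

# columnwise cosine similarity matrix: t(A) cols vs B cols
cosine_sim_matrix <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  Bn <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  crossprod(An, Bn)
}

#' Consensus clustering of signatures across bootstrap iterations
#'
#' A variation of k-means in which the N signatures of each iteration are
#' matched one-to-one to the N clusters (optimal assignment maximising total
#' cosine similarity to the current centroids), so no iteration can collapse
#' onto fewer clusters. Centroids are the renormalised averages of their
#' members; the loop runs until assignments stabilise. Because every
#' signature corresponds unambiguously to one exposure row, clustering the
#' signatures clusters the exposures too.
#'
#' @param S_P List of I signature matrices (K x N, columns normalized).
#' @param S_E List of I exposure matrices (N x G), parallel to `S_P`.
#' @param N Number of clusters (= columns of each matrix).
#' @param max_rounds Maximum assignment/update rounds.
#' @return A list: `centroids` (K x N), `exposure_centroids` (N x G),
#'   `memberships` (I x N matrix; entry (i, j) is the cluster of signature j
#'   of iteration i), `converged`.
#' @export
cluster_signatures <- function(S_P, S_E = NULL, N = ncol(S_P[[1]]),
                               max_rounds = 100L) {
  I <- length(S_P)
  stopifnot(I >= 1, all(vapply(S_P, ncol, 0L) == N))
  centroids <- S_P[[1]]
  memberships <- matrix(0L, nrow = I, ncol = N)
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    prev <- memberships
    for (i in seq_len(I)) {
      sim <- cosine_sim_matrix(S_P[[i]], centroids)
      memberships[i, ] <- solve_assignment(sim, maximize = TRUE)
    }
    # recompute centroids as member averages (renormalised to sum 1)
    for (cl in seq_len(N)) {
      members <- lapply(seq_len(I), function(i) {
        S_P[[i]][, which(memberships[i, ] == cl), drop = FALSE]
      })
      m <- do.call(cbind, members)
      cen <- rowMeans(m)
      centroids[, cl] <- cen / sum(cen)
    }
    if (identical(prev, memberships)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("consensus clustering did not stabilise after ", max_rounds,
            " rounds; returning the final assignment")
  }
  exposure_centroids <- NULL
  if (!is.null(S_E)) {
    G <- ncol(S_E[[1]])
    exposure_centroids <- matrix(0, nrow = N, ncol = G,
                                 dimnames = dimnames(S_E[[1]]))
    for (cl in seq_len(N)) {
      rows <- do.call(rbind, lapply(seq_len(I), function(i) {
        S_E[[i]][which(memberships[i, ] == cl), , drop = FALSE]
      }))
      exposure_centroids[cl, ] <- colMeans(rows)
    }
  }
  list(centroids = centroids, exposure_centroids = exposure_centroids,
       memberships = memberships, converged = converged)
}

#' Silhouette widths of a signature clustering under cosine distance
#'
#' Standard silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with
#' distance `1 - cosine_similarity`: `a(i)` is the mean distance to the
#' other members of i's cluster and `b(i)` the smallest mean distance to
#' another cluster. An average width of 1 means the same signature was
#' deciphered in every iteration; low widths indicate an irreproducible
#' solution.
#'
#' @param points K x n matrix of signature vectors (columns).
#' @param labels Integer cluster labels, length n, at least 2 clusters.
#' @return A list: `per_cluster` (named averages), `overall` (grand mean
#'   over points), `widths` (per point).
#' @export
silhouette_widths <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(labels)
  stopifnot(ncol(points) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("silhouette requires at least 2 clusters")
  }
  if (all(tabulate(labels) <= 1L)) {
    stop("silhouette undefined for singleton-only clusterings")
  }
  D <- 1 - cosine_sim_matrix(points, points)
  sil <- cluster::silhouette(labels, dmatrix = D)
  widths <- sil[, "sil_width"]
  per_cluster <- tapply(widths, labels, mean)
  list(per_cluster = per_cluster, overall = mean(widths), widths = widths)
}

#' Decipher mutational signatures from a catalog
#'
#' The full framework: (1) remove rare mutation types, (2) bootstrap the
#' reduced catalog, (3) factorize the bootstrap replicate by
#' multiplicative-update NMF, (4) repeat steps 2-3 for I iterations,
#' (5) consensus-cluster the I x N signatures into N clusters whose
#' centroids form the averaged signatures `P_bar` (with `E_bar` from the
#' corresponding exposures), and (6) evaluate reproducibility by the average
#' silhouette width under cosine distance and accuracy by the squared
#' Frobenius reconstruction error of the reduced catalog.
#'
#' Signatures are ordered by decreasing per-cluster silhouette width (most
#' reproducible first). `P_bar` is re-expanded to the full alphabet with
#' zeros in the removed rows, preserving column sums of 1. With `N = 1`
#' there is nothing to cluster; the single consensus signature is the
#' renormalised mean across iterations and its silhouette is 1 by
#' convention.
#'
#' @param M A `sig_catalog` or K x G count matrix.
#' @param cfg A `sig_decipher_config`.
#' @return A `sig_decipher_result` list: `P_bar` (K x N, columns sum to 1),
#'   `E_bar` (N x G), `P_sd` (K x N per-entry SDs across cluster members),
#'   `per_cluster_silhouette`, `avg_silhouette`, `reconstruction_error`
#'   (on the reduced matrix), `I_used`, `cluster_members`, `kept_rows`,
#'   `removed_rows`, `clustering_converged`.
#' @export
decipher_signatures <- function(M, cfg) {
  stopifnot(inherits(cfg, "sig_decipher_config"))
  labels <- NULL; samples <- NULL
  if (inherits(M, "sig_catalog")) {
    labels <- M$alphabet$labels
    samples <- M$samples
    M <- M$counts
  }
  M <- as.matrix(M)
  if (is.null(labels)) labels <- rownames(M)
  if (is.null(samples)) samples <- colnames(M)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  red <- reduce_dimensions(M, cfg$removal_threshold)
  Kdot <- nrow(red$M_dot); G <- ncol(red$M_dot)
  N <- cfg$N
  if (N > min(Kdot, G)) {
    stop("N = ", N, " exceeds min(K_dot, G) = ", min(Kdot, G))
  }

  S_P <- list(); S_E <- list()
  run_batch <- function(n_iter) {
    for (b in seq_len(n_iter)) {
      Mb <- bootstrap_catalog(red$M_dot)
      fit <- nmf_multiplicative(Mb, N, cfg$nmf, seed = NULL)
      S_P[[length(S_P) + 1L]] <<- fit$P
      S_E[[length(S_E) + 1L]] <<- fit$E
    }
  }

  if (identical(cfg$I, "auto")) {
    run_batch(cfg$auto_I_batch)
    prev_cent <- NULL
    repeat {
      cl <- cluster_signatures(S_P, NULL, N)
      if (!is.null(prev_cent) && N >= 1) {
        sim <- cosine_sim_matrix(cl$centroids, prev_cent)
        pairing <- solve_assignment(sim, maximize = TRUE)
        shift <- 1 - min(sim[cbind(seq_len(N), pairing)])
        if (shift < cfg$auto_I_tol) break
      }
      prev_cent <- cl$centroids
      if (length(S_P) >= cfg$max_I) break
      run_batch(min(cfg$auto_I_batch, cfg$max_I - length(S_P)))
    }
  } else {
    run_batch(cfg$I)
  }
  I_used <- length(S_P)

  if (N == 1L) {
    cen <- rowMeans(do.call(cbind, S_P))
    centroids <- matrix(cen / sum(cen), ncol = 1)
    exposure_centroids <- matrix(
      colMeans(do.call(rbind, S_E)), nrow = 1,
      dimnames = list(NULL, colnames(S_E[[1]])))
    memberships <- matrix(1L, nrow = I_used, ncol = 1L)
    per_sil <- 1       # convention: no second cluster exists
    avg_sil <- 1
    converged <- TRUE
  } else {
    cl <- cluster_signatures(S_P, S_E, N)
    centroids <- cl$centroids
    exposure_centroids <- cl$exposure_centroids
    memberships <- cl$memberships
    converged <- cl$converged
    pts <- do.call(cbind, S_P)
    labs <- as.integer(t(memberships))  # column j of iter i -> its cluster
    sil <- silhouette_widths(pts, labs)
    per_sil <- as.numeric(sil$per_cluster)
    avg_sil <- sil$overall
  }

  # per-entry SD of each cluster's member signatures
  P_sd_red <- matrix(0, nrow = Kdot, ncol = N)
  for (clx in seq_len(N)) {
    m <- do.call(cbind, lapply(seq_len(I_used), function(i) {
      S_P[[i]][, which(memberships[i, ] == clx), drop = FALSE]
    }))
    P_sd_red[, clx] <- if (ncol(m) > 1) apply(m, 1, stats::sd) else 0
  }

  # order signatures by decreasing reproducibility
  ordx <- order(per_sil, decreasing = TRUE)
  centroids <- centroids[, ordx, drop = FALSE]
  exposure_centroids <- exposure_centroids[ordx, , drop = FALSE]
  P_sd_red <- P_sd_red[, ordx, drop = FALSE]
  per_sil <- per_sil[ordx]

  K <- nrow(M)
  expand <- function(X) {
    full <- matrix(0, nrow = K, ncol = N)
    full[red$kept_rows, ] <- X
    full
  }
  P_bar <- expand(centroids)
  P_sd <- expand(P_sd_red)
  sig_names <- paste0("S", seq_len(N))
  dimnames(P_bar) <- dimnames(P_sd) <- list(labels, sig_names)
  dimnames(exposure_centroids) <- list(sig_names, samples)

  recon <- frobenius_error(red$M_dot, centroids, exposure_centroids)

  structure(list(
    P_bar = P_bar, E_bar = exposure_centroids, P_sd = P_sd,
    per_cluster_silhouette = per_sil, avg_silhouette = avg_sil,
    reconstruction_error = recon, I_used = I_used,
    cluster_members = memberships,
    kept_rows = red$kept_rows, removed_rows = red$removed_rows,
    clustering_converged = converged
  ), class = "sig_decipher_result")
}

#' @export
print.sig_decipher_result <- function(x, ...) {
  cat("<sig_decipher_result> N=", ncol(x$P_bar),
      ", I=", x$I_used,
      ", avg silhouette=", format(x$avg_silhouette, digits = 4),
      ", reconstruction error=", format(x$reconstruction_error, digits = 6),
      "\n", sep = "")
  cat("  per-cluster silhouettes: ",
      paste(format(x$per_cluster_silhouette, digits = 3), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
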