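# shared fixtures, all built in code

# a tiny alphabet-agnostic record table of substitutions
make_records <- function(sample, chrom, pos, ref = "C", alt = "T", ...) {
  n <- max(length(sample), length(chrom), length(pos))
  data.frame(sample = rep_len(sample, n), chrom = rep_len(chrom, n),
             pos = rep_len(pos, n), ref = rep_len(ref, n),
             alt = rep_len(alt, n), ..., stringsAsFactors = FALSE)
}

# exact low-rank factorization with well-separated signature columns
make_exact_factorization <- function(K = 12L, N = 3L, G = 8L, seed = 5L) {
  set.seed(seed)
  P <- matrix(0, K, N)
  blocks <- split(seq_len(K), rep(seq_len(N), length.out = K))
  for (n in seq_len(N)) {
    P[blocks[[n]], n] <- runif(length(blocks[[n]]), 0.5, 1)
  }
  P <- sweep(P, 2, colSums(P), "/")
  E <- matrix(runif(N * G, 50, 500), N, G)
  list(P = P, E = E, M = P %*% E)
}

# brute-force optimal assignment by permutation enumeration (N <= 6)
brute_force_assignment <- function(score) {
  n <- nrow(score)
  perms <- gtools_permutations(n)
  best <- NULL
  best_val <- -Inf
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    val <- sum(score[cbind(seq_len(n), p)])
    if (val > best_val) {
      best_val <- val
      best <- p
    }
  }
  list(assignment = best, value = best_val)
}

# all permutations of 1..n, no external dependency
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# rbind data frames with unequal column sets, filling with NA
merge_all <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[, cols, drop = FALSE]
  })
  do.call(rbind, dfs)
}
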