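# Independent oracles used to cross-check the package implementations.

# Two-sided Fisher exact probability by direct hypergeometric enumeration
# (minimum-likelihood convention, relative tolerance as in standard
# implementations).
fisher_oracle <- function(a, b, c, d) {
  m <- a + c
  n_ <- b + d
  k <- a + b
  lo <- max(0L, k - n_)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Naive O(n^3) Ward agglomeration on raw coordinates: at each step merge
# the pair of clusters with the smallest increase in within-cluster sum
# of squares (ties by smallest indices); heights on the sqrt(2 * dESS)
# scale, which is what Ward linkage on Euclidean distances reports.
naive_ward <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  members <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(members) > 1L) {
    best_cost <- Inf
    best <- c(NA, NA)
    for (i in seq_len(length(members) - 1L)) {
      for (j in seq(i + 1L, length(members))) {
        ci <- colMeans(X[members[[i]], , drop = FALSE])
        cj <- colMeans(X[members[[j]], , drop = FALSE])
        ni <- length(members[[i]])
        nj <- length(members[[j]])
        cost <- ni * nj / (ni + nj) * sum((ci - cj)^2)
        if (cost < best_cost - 1e-12) {
          best_cost <- cost
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, sqrt(2 * best_cost))
    merged <- c(members[[best[1]]], members[[best[2]]])
    members <- c(members[-best], list(merged))
    labels <- integer(n)
    for (ci in seq_along(members)) labels[members[[ci]]] <- ci
    partitions[[length(partitions) + 1L]] <- labels
  }
  list(heights = heights, partitions = partitions)
}

# Partition of n points into k clusters from the naive Ward trace.
naive_ward_cut <- function(nw, k) {
  n <- length(nw$partitions[[1]])
  nw$partitions[[n - k]]
}
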