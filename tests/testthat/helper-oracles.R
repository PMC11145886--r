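# Independent reference implementations used as oracles. These deliberately
# recompute everything from first principles and share no code with the
# package internals.

# Brute-force Ward agglomerator: at every step recomputes all pairwise
# cluster distances from the ORIGINAL dissimilarity matrix via the closed
# form h(A,B)^2 = 2 |A||B|/(|A|+|B|) * (cross - within_A/2 - within_B/2),
# where cross/within are means of squared distances over ordered pairs.
# Ties broken toward the lexicographically smallest pair of node ids.
bruteWard <- function(D) {
  n <- nrow(D)
  height <- function(A, B) {
    ca <- mean(D[A, B, drop = FALSE]^2)
    wa <- mean(D[A, A, drop = FALSE]^2)
    wb <- mean(D[B, B, drop = FALSE]^2)
    sqrt(2 * length(A) * length(B) / (length(A) + length(B)) *
           (ca - wa / 2 - wb / 2))
  }
  clusters <- as.list(seq_len(n))     # member leaves
  ids <- seq_len(n)                   # node id per active cluster
  merges <- matrix(NA_real_, n - 1, 4,
                   dimnames = list(NULL, c("left", "right", "height", "size")))
  for (s in seq_len(n - 1)) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) if (i < j) {
      h <- height(clusters[[i]], clusters[[j]])
      if (h < best[1]) best <- c(h, i, j)
    }
    i <- best[2]; j <- best[3]
    merges[s, ] <- c(min(ids[i], ids[j]), max(ids[i], ids[j]), best[1],
                     length(clusters[[i]]) + length(clusters[[j]]))
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    ids[i] <- n + s
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  merges
}

# Brute-force BH step-up: sort ascending, p(i)*n/i, cumulative min from the
# top, cap at 1, return in original order.
bruteBH <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(ord)]
}

randomDistMatrix <- function(n, seed) {
  set.seed(seed)
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.05, 2)
  D + t(D)
}

# small deterministic QuantMatrix fixture
tinyQuant <- function(values = matrix(c(8, 4, 2, 16, 1, 32), 2, 3),
                      ids = c("P1", "P2"), samples = c("s1", "s2", "s3"),
                      scale = "raw") {
  dimnames(values) <- list(ids, samples)
  QuantMatrix(values, scale = scale)
}

# fast desk-scale simulation for pipeline-level tests
smallSimConfig <- function(seed = 1L, effect_size = 1.5, ...) {
  simConfig(n_samples = 60L, class_counts = c(33L, 27L), n_blocks = 6L,
            block_size = 5L, within_block_correlation = 0.8,
            informative_blocks = c(1L, 2L), effect_size = effect_size,
            n_batches = 2L, missing_rate = 0, zero_rate = 0,
            multi_id_fraction = 0, seed = seed, ...)
}
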