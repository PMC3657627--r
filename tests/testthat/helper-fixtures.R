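# Shared fixtures and independent oracles for the test suite.

# A small valid decomposition with random content (not class-structured).
tiny_decomposition <- function(K = 3L, N = 32L, grid = c(4L, 4L, 4L),
                               tr = 2, seed = 42L) {
  set.seed(seed)
  mask <- array(TRUE, dim = grid)
  M <- sum(mask)
  ica_decomposition(matrix(rnorm(N * K), N, K),
                    matrix(rnorm(K * M), K, M), mask, tr)
}

# Direct per-point silhouette by plain loops over pairwise distances;
# independent of the package's implementation.
sil_direct <- function(i, values, labels) {
  own <- labels[i]
  mates <- which(labels == own & seq_along(values) != i)
  if (!length(mates)) return(0)
  a <- mean(abs(values[mates] - values[i]))
  b <- Inf
  for (k in setdiff(unique(labels), own)) {
    b <- min(b, mean(abs(values[labels == k] - values[i])))
  }
  if (max(a, b) == 0) return(0)
  (b - a) / max(a, b)
}

# Exhaustive 1-D k-means oracle: for each candidate k, enumerate every
# contiguous partition of the sorted values (the optimal k-means
# assignment in one dimension is always contiguous), take the partition
# with minimal within-cluster sum of squares, and score it by the
# directly computed mean silhouette. Returns the k with maximal mean
# silhouette, ties toward smaller k.
oracle_choose_k <- function(values, k_candidates) {
  n <- length(values)
  ord <- order(values)
  v <- values[ord]
  best <- NULL
  for (k in sort(k_candidates[k_candidates <= length(unique(values))])) {
    cuts <- if (k == 1L) matrix(integer(0), 0, 1) else
      utils::combn(n - 1L, k - 1L)
    best_wss <- Inf
    best_labels <- NULL
    for (j in seq_len(ncol(cuts))) {
      bounds <- c(0L, cuts[, j], n)
      lab_sorted <- rep(seq_len(k), diff(bounds))
      wss <- sum(vapply(split(v, lab_sorted),
                        function(g) sum((g - mean(g))^2), numeric(1)))
      if (wss < best_wss - 1e-12) {
        best_wss <- wss
        best_labels <- lab_sorted
      }
    }
    labels <- integer(n)
    labels[ord] <- best_labels
    sil <- mean(vapply(seq_len(n), function(i) sil_direct(i, values, labels),
                       numeric(1)))
    if (is.null(best) || sil > best$mean_silhouette + 1e-12) {
      best <- list(k = k, labels = labels, mean_silhouette = sil)
    }
  }
  best
}

# Skip-less quiet pipeline runner (demotion messages silenced).
quiet_pipeline <- function(dec, tissue, cfg = selection_config()) {
  suppressMessages(run_pipeline(dec, tissue, cfg))
}
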