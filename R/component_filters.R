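#' Pearson's median skewness coefficient
#'
#' `3 * (mean - median) / sd`, with `sd` the sample (n-1) standard
#' deviation. Symmetric (noise-like) value distributions score near 0;
#' spatial maps carrying localised activation are strongly skewed. A
#' constant vector (zero variance) carries no network structure and is
#' scored 0, i.e. maximally noise-like.
#'
#' @param values numeric vector of length >= 2.
#' @return a single dimensionless number.
#' @export
pearson_coefficient <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("pearson_coefficient needs at least 2 values", call. = FALSE)
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(0)
  3 * (mean(values) - stats::median(values)) / s
}

#' Step 1: skewness-based component rejection
#'
#' Computes the Pearson median skewness coefficient of each component's
#' spatial map (row of the source matrix) and rejects the components whose
#' coefficient is strictly below the threshold TH. By default TH is the
#' median of the per-component coefficients (absolute values under the
#' default `skewness_mode = "absolute"`, so strongly left-skewed maps are
#' kept too); a fixed threshold can be supplied via
#' `cfg$skewness_threshold_override`. Components exactly at TH survive.
#'
#' @param dec an [ica_decomposition()].
#' @param cfg a [selection_config()].
#' @return list of `component_state`, one per component in original order,
#'   with attribute `"threshold"` carrying the TH actually used.
#' @export
skewness_filter <- function(dec, cfg = selection_config()) {
  K <- ncol(dec$mixing)
  if (K == 0L) stop("decomposition has no components", call. = FALSE)
  M <- ncol(dec$sources)
  coefs <- apply(dec$sources, 1L, pearson_coefficient)
  compared <- if (cfg$skewness_mode == "absolute") abs(coefs) else coefs
  th <- if (!is.null(cfg$skewness_threshold_override)) {
    as.numeric(cfg$skewness_threshold_override)
  } else {
    stats::median(compared)
  }
  states <- lapply(seq_len(K), function(i) {
    st <- new_component_state(i, M)
    st$pearson_coefficient <- coefs[i]
    if (compared[i] < th) {
      st <- reject_state(st, "rejected_skewness", "skewness")
      st$retained_voxels[] <- FALSE
    }
    st
  })
  attr(states, "threshold") <- th
  states
}

#' Silhouette index of a single point
#'
#' `(b - a) / max(a, b)` where `a` is the point's average distance to the
#' other members of its own cluster and `b` the smallest average distance
#' to the members of any other cluster. Distances are one-dimensional
#' Euclidean (absolute differences of activation values). A point alone in
#' its cluster scores 0 by convention.
#'
#' @param point_index index (1-based) of the point to score.
#' @param values numeric vector of activation values.
#' @param labels integer cluster labels, same length as `values`; at least
#'   two distinct clusters must be present.
#' @return silhouette value in [-1, 1].
#' @export
silhouette_value <- function(point_index, values, labels) {
  values <- as.numeric(values)
  labels <- as.integer(labels)
  stopifnot(length(values) == length(labels),
            point_index >= 1L, point_index <= length(values))
  clusters <- unique(labels)
  if (length(clusters) < 2L) {
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  }
  own <- labels[point_index]
  mates <- setdiff(which(labels == own), point_index)
  if (!length(mates)) return(0)
  x <- values[point_index]
  a <- mean(abs(values[mates] - x))
  b <- min(vapply(setdiff(clusters, own),
                  function(k) mean(abs(values[labels == k] - x)),
                  numeric(1)))
  if (max(a, b) == 0) return(0)
  (b - a) / max(a, b)
}

# Mean silhouette over the points in score_idx, exact but O(n log n) per
# cluster: per-cluster sorted prefix sums give every point's summed
# absolute distance to a cluster in closed form.
mean_silhouette <- function(values, labels, score_idx = seq_along(values)) {
  clusters <- sort(unique(labels))
  stopifnot(length(clusters) >= 2L)
  info <- lapply(clusters, function(k) {
    v <- sort(values[labels == k])
    list(v = v, cs = c(0, cumsum(v)), n = length(v))
  })
  x <- values[score_idx]
  lx <- labels[score_idx]
  # dist_sum[j, c] = sum over cluster c members of |x_j - member|
  dist_sum <- vapply(info, function(cl) {
    pos <- findInterval(x, cl$v)
    below <- cl$cs[pos + 1L]
    total <- cl$cs[cl$n + 1L]
    pos * x - below + (total - below) - (cl$n - pos) * x
  }, numeric(length(x)))
  dist_sum <- matrix(dist_sum, nrow = length(x))
  sil <- numeric(length(x))
  for (j in seq_along(clusters)) {
    sel <- lx == clusters[j]
    if (!any(sel)) next
    n_own <- info[[j]]$n
    if (n_own <= 1L) { sil[sel] <- 0; next }
    a <- dist_sum[sel, j] / (n_own - 1L)
    others <- setdiff(seq_along(clusters), j)
    b_cols <- vapply(others, function(m) dist_sum[sel, m] / info[[m]]$n,
                     numeric(sum(sel)))
    b <- if (length(others) == 1L) as.numeric(b_cols)
         else apply(matrix(b_cols, nrow = sum(sel)), 1L, min)
    mx <- pmax(a, b)
    sil[sel] <- ifelse(mx > 0, (b - a) / mx, 0)
  }
  mean(sil)
}

#' Choose the number of clusters by maximum mean silhouette
#'
#' Runs one-dimensional k-means (Euclidean distance on activation values)
#' for every candidate `k` and returns the solution with the largest mean
#' silhouette index, ties broken toward smaller `k`. Clustering is
#' deterministic given `cfg$kmeans_seed` (the seed drives both the k-means
#' restarts and, on inputs larger than `cfg$silhouette_subsample`, the
#' subsample of points scored by the silhouette; below the cap the
#' silhouette is exact).
#'
#' @param values numeric vector of activation values; must contain at
#'   least `min(k_candidates)` distinct values.
#' @param cfg a [selection_config()].
#' @return An object of class `cluster_solution` with fields `k`, `labels`
#'   (1-based, in `values` order), `centroids`, and `mean_silhouette`.
#' @export
choose_k <- function(values, cfg = selection_config()) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("choose_k: values must be finite", call. = FALSE)
  }
  n_distinct <- length(unique(values))
  kc <- sort(unique(cfg$k_candidates))
  kc <- kc[kc <= n_distinct]
  if (!length(kc) || diff(range(values)) < 1e-12) {
    stop(sprintf(
      "choose_k: only %d distinct value(s); no candidate k >= 2 is feasible",
      n_distinct), call. = FALSE)
  }
  score_idx <- if (length(values) > cfg$silhouette_subsample) {
    with_seed(cfg$kmeans_seed,
              sort(sample.int(length(values), cfg$silhouette_subsample)))
  } else {
    seq_along(values)
  }
  best <- NULL
  for (k in kc) {
    km <- with_seed(cfg$kmeans_seed + k, tryCatch(
      suppressWarnings(stats::kmeans(values, centers = k,
                                     iter.max = 300L, nstart = 10L)),
      error = function(e) NULL))
    if (is.null(km)) next
    sil <- mean_silhouette(values, km$cluster, score_idx)
    if (is.null(best) || sil > best$mean_silhouette) {
      best <- structure(list(
        k = k,
        labels = as.integer(km$cluster),
        centroids = as.numeric(km$centers),
        mean_silhouette = sil
      ), class = "cluster_solution")
    }
  }
  if (is.null(best)) {
    stop("choose_k: k-means failed for every candidate k", call. = FALSE)
  }
  best
}

#' Step 2: k-means voxel filtering
#'
#' Clusters the component's currently retained voxel values with
#' [choose_k()] and removes the voxels of the single cluster whose
#' centroid is nearest to 0 — the lowest-activation voxels. If clustering
#' is impossible (degenerate, near-constant values) the component is
#' demoted to `rejected_empty` with a logged reason instead of aborting.
#'
#' @param state a candidate `component_state` (survived step 1).
#' @param dec the [ica_decomposition()].
#' @param cfg a [selection_config()].
#' @return the updated `component_state`.
#' @export
cluster_filter <- function(state, dec, cfg = selection_config()) {
  stopifnot(inherits(state, "component_state"))
  if (state$status != "candidate") {
    stop("cluster_filter applies only to candidate components", call. = FALSE)
  }
  idx <- which(state$retained_voxels)
  vals <- dec$sources[state$index, idx]
  sol <- tryCatch(choose_k(vals, cfg), error = function(e) e)
  if (inherits(sol, "error")) {
    state <- reject_state(state, "rejected_empty", "clustering",
                          conditionMessage(sol))
    state$retained_voxels[] <- FALSE
    state$n_after_clustering <- 0L
    return(state)
  }
  drop <- which.min(abs(sol$centroids))
  state$retained_voxels[idx[sol$labels == drop]] <- FALSE
  state$n_after_clustering <- sum(state$retained_voxels)
  state$chosen_k <- sol$k
  if (state$n_after_clustering == 0L) {
    state <- reject_state(state, "rejected_empty", "clustering",
                          "no voxels left after removing the near-zero cluster")
  }
  state
}

#' Step 3: tissue-probability voxel masking
#'
#' Removes retained voxels that are confidently non-gray-matter: under the
#' default `either_map` rule, a voxel is cancelled when its white-matter
#' OR its CSF probability reaches `cfg$tissue_prob_threshold` (default
#' 0.9); under the `summed` rule, when WM + CSF reaches it. A component
#' whose retained set empties is demoted to `rejected_empty`.
#'
#' @param state a candidate `component_state` (survived steps 1-2).
#' @param tissue a [tissue_maps()] on the decomposition grid.
#' @param dec the [ica_decomposition()] (supplies the brain mask that maps
#'   retained-voxel indices onto the grid).
#' @param cfg a [selection_config()].
#' @return the updated `component_state`.
#' @export
tissue_filter <- function(state, tissue, dec, cfg = selection_config()) {
  stopifnot(inherits(state, "component_state"),
            inherits(tissue, "tissue_maps"))
  if (!identical(tissue$grid_shape, dec$grid_shape)) {
    stop(sprintf(
      "tissue grid %s does not match decomposition grid %s",
      paste(tissue$grid_shape, collapse = "x"),
      paste(dec$grid_shape, collapse = "x")), call. = FALSE)
  }
  if (state$status != "candidate") {
    stop("tissue_filter applies only to candidate components", call. = FALSE)
  }
  wm_v <- tissue$wm[dec$mask]
  csf_v <- tissue$csf[dec$mask]
  th <- cfg$tissue_prob_threshold
  cancel <- if (cfg$tissue_rule == "either_map") {
    wm_v >= th | csf_v >= th
  } else {
    (wm_v + csf_v) >= th
  }
  state$retained_voxels <- state$retained_voxels & !cancel
  state$n_after_segmentation <- sum(state$retained_voxels)
  if (state$n_after_segmentation == 0L) {
    state <- reject_state(state, "rejected_empty", "segmentation",
                          "all retained voxels fall in high-probability WM/CSF")
  }
  state
}
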