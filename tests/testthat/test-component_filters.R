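test_that("pearson_coefficient matches hand-computed values", {
  expect_equal(pearson_coefficient(c(-1, 0, 1)), 0)
  # mean 0.25, median 0, sample sd 0.5 -> 3 * 0.25 / 0.5
  expect_equal(pearson_coefficient(c(0, 0, 0, 1)), 1.5)
  expect_equal(pearson_coefficient(rep(3, 10)), 0)   # zero variance
  expect_error(pearson_coefficient(1), "at least 2")
})

test_that("pearson_coefficient is near 0 for symmetric samples, scale-invariant, sign-antisymmetric", {
  set.seed(101)
  x <- rnorm(1e5)
  expect_lt(abs(pearson_coefficient(x)), 0.05)
  y <- rexp(500)                                    # strongly skewed
  expect_equal(pearson_coefficient(y * 7.3), pearson_coefficient(y),
               tolerance = 1e-12)
  expect_equal(pearson_coefficient(-y), -pearson_coefficient(y),
               tolerance = 1e-12)
})

test_that("skewness_filter thresholds at the median coefficient, keeping exact ties", {
  set.seed(21)
  mask <- array(TRUE, c(5L, 5L, 4L))
  M <- sum(mask)
  # rows of varying skew: mixtures of exponential and Gaussian values
  w <- c(0, 0.05, 0.4, 0.9)
  S <- t(sapply(w, function(wi) (1 - wi) * rnorm(M) + wi * rexp(M)))
  dec <- ica_decomposition(matrix(rnorm(40 * 4), 40, 4), S, mask, 2)
  states <- skewness_filter(dec)
  coefs <- sapply(states, function(s) s$pearson_coefficient)
  expect_equal(coefs, apply(S, 1, pearson_coefficient))
  th <- attr(states, "threshold")
  expect_equal(th, median(abs(coefs)))
  statuses <- sapply(states, function(s) s$status)
  expect_identical(statuses == "candidate", abs(coefs) >= th)
  expect_identical(sapply(states, function(s) s$index), 1:4)

  # identical rows: every coefficient equals TH, none strictly below
  S_tie <- matrix(rep(S[4, ], 3), nrow = 3, byrow = TRUE)
  dec_tie <- ica_decomposition(matrix(rnorm(40 * 3), 40, 3), S_tie, mask, 2)
  st_tie <- skewness_filter(dec_tie)
  expect_true(all(sapply(st_tie, function(s) s$status) == "candidate"))

  # K = 1: TH equals the single coefficient, the component survives
  dec_one <- ica_decomposition(matrix(rnorm(40), 40, 1),
                               S[1, , drop = FALSE], mask, 2)
  expect_identical(skewness_filter(dec_one)[[1]]$status, "candidate")

  # a fixed override replaces the median rule
  cfg_ov <- selection_config(skewness_threshold_override = 100)
  st_ov <- skewness_filter(dec, cfg_ov)
  expect_true(all(sapply(st_ov, function(s) s$status) == "rejected_skewness"))
})

test_that("silhouette_value matches hand computation and boundary conventions", {
  # a = 1, b = (10 + 11)/2 = 10.5 -> (10.5 - 1)/10.5
  expect_equal(silhouette_value(1, c(0, 1, 10, 11), c(1, 1, 2, 2)),
               9.5 / 10.5)
  # coincident in-cluster points: a = 0 -> silhouette 1
  expect_equal(silhouette_value(1, c(5, 5, 20), c(1, 1, 2)), 1)
  # singleton cluster convention
  expect_equal(silhouette_value(3, c(0, 1, 10), c(1, 1, 2)), 0)
  expect_error(silhouette_value(1, c(0, 1, 2), c(1, 1, 1)),
               "at least 2 clusters")
})

test_that("silhouette agrees with a direct pairwise implementation and with cluster::silhouette", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    values <- rnorm(n, sd = 5)
    k <- sample(2:4, 1)
    labels <- sample(seq_len(k), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    direct <- vapply(seq_len(n), function(i) sil_direct(i, values, labels),
                     numeric(1))
    mine <- vapply(seq_len(n),
                   function(i) silhouette_value(i, values, labels),
                   numeric(1))
    expect_equal(mine, direct, tolerance = 1e-10)
    expect_equal(rsnselect:::mean_silhouette(values, labels), mean(direct),
                 tolerance = 1e-10)
    # independent library cross-check (identical conventions incl. singletons)
    ref <- cluster::silhouette(labels, dist(values))
    expect_equal(mine, as.numeric(ref[, "sil_width"]), tolerance = 1e-10)
  }
})

test_that("choose_k recovers the silhouette-optimal k on structured data", {
  cfg23 <- selection_config(k_candidates = 2:3)
  sol <- choose_k(c(0, 0.1, 5, 5.1, 10, 10.2), cfg23)
  expect_identical(sol$k, 3L)
  sol2 <- choose_k(c(0, 0, 0, 10, 10, 10), selection_config())
  expect_identical(sol2$k, 2L)
  expect_equal(sort(sol2$centroids), c(0, 10))
  expect_equal(sol2$mean_silhouette, 1)
  expect_error(choose_k(rep(1, 10) + 1e-13 * runif(10), selection_config()),
               "distinct")
  # centroids are the means of their members
  set.seed(9)
  v <- c(rnorm(30), rnorm(30, 8))
  sol3 <- choose_k(v, selection_config(k_candidates = 2:4))
  for (k in seq_len(sol3$k)) {
    expect_equal(sol3$centroids[k], mean(v[sol3$labels == k]),
                 tolerance = 1e-8)
  }
})

test_that("choose_k is bit-reproducible under a fixed seed and honours the subsample cap", {
  set.seed(77)
  v <- c(rnorm(4000), rnorm(4000, 6))
  cfg <- selection_config(k_candidates = 2:4, silhouette_subsample = 500L)
  a <- choose_k(v, cfg)
  b <- choose_k(v, cfg)
  expect_identical(a, b)
  # the RNG state of the caller is untouched
  before <- .Random.seed
  choose_k(v, cfg)
  expect_identical(.Random.seed, before)
})

test_that("cluster_filter removes exactly the cluster with centroid nearest zero", {
  mask <- array(TRUE, c(2L, 2L, 1L))
  mk <- function(vals) {
    ica_decomposition(matrix(rnorm(16), 16, 1), matrix(vals, 1), mask, 2)
  }
  cfg <- selection_config(k_candidates = 2:3)
  st <- rsnselect:::new_component_state(1L, 4L)
  st$pearson_coefficient <- 1

  out <- cluster_filter(st, mk(c(0, 1, 10, 11)), cfg)
  expect_identical(out$retained_voxels, c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(out$n_after_clustering, 2L)

  # |centroid| rule: the negative cluster at -10.5 is kept
  out2 <- cluster_filter(st, mk(c(-10, -11, 0, 1)), cfg)
  expect_identical(out2$retained_voxels, c(TRUE, TRUE, FALSE, FALSE))

  # near-degenerate pair of tight clouds: no crash, one cloud removed
  out3 <- cluster_filter(st, mk(c(5, 5, 5.001, 5.001)), cfg)
  expect_identical(out3$status, "candidate")
  expect_identical(sum(out3$retained_voxels), 2L)

  # degenerate values demote rather than abort
  expect_message(
    out4 <- cluster_filter(st, mk(rep(2, 4)), cfg),
    "rejected at clustering")
  expect_identical(out4$status, "rejected_empty")
})

test_that("tissue_filter cancels confident WM/CSF voxels under either_map and summed rules", {
  grid <- c(2L, 2L, 1L)
  mask <- array(TRUE, grid)
  dec <- ica_decomposition(matrix(rnorm(16), 16, 1),
                           matrix(rnorm(4), 1), mask, 2)
  gm <- array(0, grid)
  wm <- array(c(0.95, 0.89, 0, 0.5), grid)
  csf <- array(c(0, 0.05, 0.91, 0.45), grid)
  tm <- tissue_maps(gm, wm, csf)
  st <- rsnselect:::new_component_state(1L, 4L)

  out <- tissue_filter(st, tm, dec)
  # wm 0.95 removed; wm 0.89 retained under either_map; csf 0.91 removed
  expect_identical(out$retained_voxels, c(FALSE, TRUE, FALSE, TRUE))

  out_sum <- tissue_filter(st, tm, dec, selection_config(tissue_rule = "summed"))
  expect_identical(out_sum$retained_voxels, c(FALSE, FALSE, FALSE, FALSE))
  expect_identical(out_sum$status, "rejected_empty")
  expect_identical(out_sum$rejection_stage, "segmentation")

  # all-zero tissue maps leave the retained set unchanged
  zero <- tissue_maps(gm, array(0, grid), array(0, grid))
  expect_identical(tissue_filter(st, zero, dec)$retained_voxels,
                   rep(TRUE, 4))

  wrong <- tissue_maps(array(0, c(3, 3, 3)), array(0, c(3, 3, 3)),
                       array(0, c(3, 3, 3)))
  expect_error(tissue_filter(st, wrong, dec), "does not match")
})

test_that("retained-voxel sets shrink monotonically through steps 2 and 3", {
  fix <- make_decomposition(seed = 17)
  states <- skewness_filter(fix$decomposition)
  for (st in states) {
    if (st$status != "candidate") next
    n0 <- sum(st$retained_voxels)
    st2 <- suppressMessages(cluster_filter(st, fix$decomposition))
    expect_lte(sum(st2$retained_voxels), n0)
    if (st2$status != "candidate") next
    st3 <- suppressMessages(tissue_filter(st2, fix$tissue, fix$decomposition))
    expect_lte(sum(st3$retained_voxels), sum(st2$retained_voxels))
    expect_true(all(st3$retained_voxels <= st2$retained_voxels))
  }
})
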