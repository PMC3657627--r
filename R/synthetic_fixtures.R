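#' Synthetic tissue probability maps
#'
#' Builds a smooth spherical head phantom on the given grid: a
#' white-matter core, a gray-matter shell around it, and two small
#' ventricle blobs of near-certain CSF at the centre. Probabilities are
#' smooth, lie in [0, 1], and sum to at most 1 at every voxel. The brain
#' mask is the sphere of radius `0.45 * min(grid)` around the grid centre.
#'
#' @param grid_shape integer triple (default `c(20, 20, 20)`).
#' @return list with elements `tissue` (a [tissue_maps()]) and `mask`
#'   (logical 3-D array).
#' @export
simulate_tissue_maps <- function(grid_shape = c(20L, 20L, 20L)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L))
  ctr <- (grid_shape + 1) / 2
  ax <- lapply(1:3, function(d) seq_len(grid_shape[d]) - ctr[d])
  dist_to <- function(offset) {
    dx2 <- (ax[[1]] - offset[1])^2
    dy2 <- (ax[[2]] - offset[2])^2
    dz2 <- (ax[[3]] - offset[3])^2
    sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
  }
  r <- dist_to(c(0, 0, 0))
  rv <- pmin(dist_to(c(-2, 0, 0)), dist_to(c(2, 0, 0)))   # ventricles
  scale <- min(grid_shape) / 20                            # phantom scale
  csf <- 0.96 * exp(-pmax(rv / scale - 2, 0)^2 / 1.5)
  wm <- 0.95 * exp(-pmax(r / scale - 4.5, 0)^2 / 2) * (1 - csf)
  gm <- pmax(0.92 * exp(-(r / scale - 7)^2 / 2) * (1 - csf - wm), 0)
  mask <- r <= 0.45 * min(grid_shape)
  list(tissue = tissue_maps(gm, wm, csf), mask = mask)
}

# Frequency-bin synthesis of a unit-variance time course whose power is
# concentrated on the periodogram bins with frequency in [f_lo, f_hi],
# plus a small broadband admixture.
band_limited_course <- function(n, tr, f_lo, f_hi, broadband_sd = 0.15) {
  freqs <- seq_len(n %/% 2L) / (n * tr)
  bins <- which(freqs >= f_lo & freqs <= f_hi)
  tt <- seq_len(n) - 1
  x <- numeric(n)
  for (k in bins) {
    x <- x + stats::rnorm(1) * cos(2 * pi * k * tt / n) +
             stats::rnorm(1) * sin(2 * pi * k * tt / n)
  }
  x <- x / stats::sd(x) + stats::rnorm(n, sd = broadband_sd)
  x / stats::sd(x)
}

#' Generate a ground-truth synthetic decomposition
#'
#' Emulates the decomposition a spatial ICA of resting-state fMRI would
#' produce, with three known component classes so every selection stage
#' can be tested against ground truth:
#'
#' * network components: spatial maps with 2-3 ellipsoidal blobs of
#'   positive folded-Gaussian activation placed in the gray-matter shell
#'   over a symmetric unit-variance background (strongly right-skewed);
#'   time courses band-limited to the resting-state band (about 98% of
#'   power inside 0.01-0.1 Hz).
#' * Gaussian-noise components: zero-mean symmetric maps (skewness near
#'   0) with broadband white time courses.
#' * CSF components: activation confined to voxels with CSF probability
#'   >= 0.9 (the phantom ventricles); time courses dominated by
#'   frequencies above 0.1 Hz, mimicking pulsation aliases.
#'
#' Component order is randomly permuted so class is not inferable from the
#' index. The defaults mirror a typical single-subject resting-state
#' acquisition: 197 volumes at TR = 2 s on a 20^3 grid.
#'
#' @param n_network,n_noise,n_csf per-class component counts
#'   (defaults 3, 7, 2).
#' @param grid_shape integer triple (default `c(20, 20, 20)`).
#' @param n_timepoints number of volumes N (default 197).
#' @param tr_seconds repetition time (default 2).
#' @param blob_radius network blob radius in voxels (default 4).
#' @param activation_scale amplitude of blob / CSF activation relative to
#'   the unit-SD map background (default 12).
#' @param map_noise_sd SD of the symmetric map background (default 1).
#' @param seed integer; fully determines all outputs.
#' @return list with elements `decomposition` ([ica_decomposition()]),
#'   `tissue` ([tissue_maps()]), and `truth` (class `ground_truth`, with
#'   `network_indices`, `gaussian_noise_indices`, `csf_indices` and the
#'   generator parameters).
#' @export
make_decomposition <- function(n_network = 3L, n_noise = 7L, n_csf = 2L,
                               grid_shape = c(20L, 20L, 20L),
                               n_timepoints = 197L, tr_seconds = 2,
                               blob_radius = 4, activation_scale = 12,
                               map_noise_sd = 1, seed = 1L) {
  n_network <- as.integer(n_network)
  n_noise <- as.integer(n_noise)
  n_csf <- as.integer(n_csf)
  stopifnot(n_network >= 0L, n_noise >= 0L, n_csf >= 0L)
  K <- n_network + n_noise + n_csf
  if (K == 0L) stop("at least one component must be requested", call. = FALSE)
  if (2 * blob_radius >= min(grid_shape)) {
    stop(sprintf("blob radius %g does not fit in grid %s", blob_radius,
                 paste(grid_shape, collapse = "x")), call. = FALSE)
  }
  phantom <- simulate_tissue_maps(grid_shape)
  mask <- phantom$mask
  tissue <- phantom$tissue
  M <- sum(mask)
  ctr <- (grid_shape + 1) / 2
  vox <- which(mask, arr.ind = TRUE)            # M x 3, column-major order
  csf_vox <- tissue$csf[mask] >= 0.9
  shell_radius <- 0.35 * min(grid_shape)        # blob centres in GM shell

  with_seed(seed, {
    classes <- sample(rep(c("network", "noise", "csf"),
                          c(n_network, n_noise, n_csf)))
    S <- matrix(0, nrow = K, ncol = M)
    A <- matrix(0, nrow = n_timepoints, ncol = K)
    for (i in seq_len(K)) {
      map <- stats::rnorm(M, sd = map_noise_sd)
      if (classes[i] == "network") {
        for (b in seq_len(sample(2:3, 1))) {
          u <- stats::rnorm(3)
          centre <- ctr + shell_radius * u / sqrt(sum(u^2))
          d <- sqrt((vox[, 1] - centre[1])^2 + (vox[, 2] - centre[2])^2 +
                    (vox[, 3] - centre[3])^2)
          inside <- d <= blob_radius
          if (!any(inside)) next
          envelope <- exp(-d[inside]^2 / (2 * blob_radius^2))
          map[inside] <- map[inside] +
            activation_scale * envelope * abs(stats::rnorm(sum(inside)))
        }
        A[, i] <- band_limited_course(n_timepoints, tr_seconds,
                                      0.012, 0.095, broadband_sd = 0.15)
      } else if (classes[i] == "csf") {
        if (any(csf_vox)) {
          map[csf_vox] <- map[csf_vox] +
            activation_scale * abs(stats::rnorm(sum(csf_vox)))
        }
        f_hi <- 0.96 / (2 * tr_seconds)
        A[, i] <- band_limited_course(n_timepoints, tr_seconds,
                                      0.105, f_hi, broadband_sd = 0.15)
      } else {
        A[, i] <- stats::rnorm(n_timepoints)
      }
      S[i, ] <- map
    }
    dec <- ica_decomposition(A, S, mask, tr_seconds)
    truth <- structure(list(
      network_indices = which(classes == "network"),
      gaussian_noise_indices = which(classes == "noise"),
      csf_indices = which(classes == "csf"),
      grid_shape = as.integer(grid_shape),
      n_timepoints = as.integer(n_timepoints),
      tr_seconds = tr_seconds,
      blob_radius = blob_radius,
      activation_scale = activation_scale,
      map_noise_sd = map_noise_sd,
      seed = as.integer(seed)
    ), class = "ground_truth")
    list(decomposition = dec, tissue = tissue, truth = truth)
  })
}

#' Mix a decomposition back to a 4-D data volume
#'
#' Forms `X = A S + E` with `E` i.i.d. zero-mean Gaussian noise of the
#' given standard deviation, and scatters each time point onto the grid
#' (out-of-mask voxels are 0). With `noise_sigma = 0` every in-mask voxel
#' time series equals the exact mixture.
#'
#' @param dec an [ica_decomposition()].
#' @param noise_sigma standard deviation of the additive Gaussian noise
#'   (default 0).
#' @param seed integer seed for the noise draw (default 1).
#' @return 4-D numeric array, `grid_shape x N`.
#' @export
mix_to_4d <- function(dec, noise_sigma = 0, seed = 1L) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  X <- dec$mixing %*% dec$sources                # N x M
  if (noise_sigma > 0) {
    X <- X + with_seed(seed,
      matrix(stats::rnorm(length(X), sd = noise_sigma), nrow = nrow(X)))
  }
  n <- nrow(X)
  out <- array(0, dim = c(dec$grid_shape, n))
  flat <- matrix(out, ncol = n)
  flat[which(dec$mask), ] <- t(X)
  array(flat, dim = c(dec$grid_shape, n))
}
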