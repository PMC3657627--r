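#' ICA decomposition container
#'
#' Bundles the two matrices of the spatial-ICA data model `X = A S + E`
#' together with the brain mask and the repetition time. `mixing` is the
#' `N x K` matrix `A` of component time courses (one column per component);
#' `sources` is the `K x M` matrix `S` of spatial maps, one row per
#' component, whose columns cover only the `M` in-mask voxels.
#'
#' In-mask voxels are linearised in R's native column-major order (first
#' axis fastest), i.e. `values[mask]`; this fixed ordering is what maps
#' source-matrix columns back to grid positions, see
#' [voxels_to_grid()] / [grid_to_voxels()].
#'
#' @param mixing numeric matrix, time points x components.
#' @param sources numeric matrix, components x in-mask voxels.
#' @param mask logical 3-D array; `sum(mask)` must equal `ncol(sources)`.
#' @param tr_seconds repetition time (sampling interval) in seconds.
#' @return An object of class `ica_decomposition` with fields `mixing`,
#'   `sources`, `mask`, `tr_seconds`, `grid_shape`.
#' @seealso [validate_decomposition()], [read_decomposition()]
#' @export
ica_decomposition <- function(mixing, sources, mask, tr_seconds) {
  mixing <- as.matrix(mixing)
  storage.mode(mixing) <- "double"
  sources <- as.matrix(sources)
  storage.mode(sources) <- "double"
  mask <- array(as.logical(mask), dim = dim(mask))
  dec <- structure(
    list(mixing = mixing, sources = sources, mask = mask,
         tr_seconds = as.numeric(tr_seconds)[1], grid_shape = dim(mask)),
    class = "ica_decomposition")
  violations <- validate_decomposition(dec)
  if (length(violations)) {
    stop("invalid ICA decomposition:\n  - ",
         paste(violations, collapse = "\n  - "), call. = FALSE)
  }
  dec
}

#' Validate an ICA decomposition
#'
#' Checks every structural invariant of the decomposition and returns the
#' violations as a character vector (empty when the object is valid).
#' Validation is total: it reports problems, it never throws.
#'
#' @param dec an object shaped like an [ica_decomposition()].
#' @return character vector of violation descriptions; `character(0)` if
#'   the object is valid.
#' @export
validate_decomposition <- function(dec) {
  v <- character(0)
  if (!is.list(dec)) return("decomposition: not a list")
  need <- c("mixing", "sources", "mask", "tr_seconds")
  missing <- setdiff(need, names(dec))
  if (length(missing)) {
    return(sprintf("decomposition: missing field '%s'", missing))
  }
  if (!is.matrix(dec$mixing) || !is.numeric(dec$mixing)) {
    v <- c(v, "mixing: not a numeric matrix")
  }
  if (!is.matrix(dec$sources) || !is.numeric(dec$sources)) {
    v <- c(v, "sources: not a numeric matrix")
  }
  if (!is.array(dec$mask) || length(dim(dec$mask)) != 3L ||
      !is.logical(dec$mask)) {
    v <- c(v, "mask: not a logical 3-D array")
  }
  if (length(v)) return(v)

  if (ncol(dec$mixing) != nrow(dec$sources)) {
    v <- c(v, sprintf(
      "component count mismatch: mixing has %d columns but sources has %d rows",
      ncol(dec$mixing), nrow(dec$sources)))
  }
  m_mask <- sum(dec$mask)
  if (ncol(dec$sources) != m_mask) {
    v <- c(v, sprintf(
      "voxel count mismatch: sources has %d columns but mask has %d true voxels",
      ncol(dec$sources), m_mask))
  }
  tr <- dec$tr_seconds
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    v <- c(v, "tr_seconds: must be a single positive finite number")
  }
  if (anyNA(dec$mixing) || any(!is.finite(dec$mixing))) {
    v <- c(v, "mixing: contains non-finite values")
  }
  if (anyNA(dec$sources) || any(!is.finite(dec$sources))) {
    v <- c(v, "sources: contains non-finite values")
  }
  v
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf(
    "ICA decomposition: K = %d components, N = %d time points, M = %d in-mask voxels\n",
    ncol(x$mixing), nrow(x$mixing), ncol(x$sources)))
  cat(sprintf("  grid %s, TR = %g s (Nyquist %.4g Hz)\n",
              paste(x$grid_shape, collapse = " x "), x$tr_seconds,
              1 / (2 * x$tr_seconds)))
  invisible(x)
}

#' Extract in-mask voxel values from a 3-D grid
#'
#' @param grid numeric 3-D array on the decomposition grid.
#' @param mask logical 3-D array of the same shape.
#' @return numeric vector of length `sum(mask)` in the package's fixed
#'   column-major voxel order.
#' @export
grid_to_voxels <- function(grid, mask) {
  stopifnot(identical(dim(grid), dim(mask)))
  as.numeric(grid[mask])
}

#' Scatter in-mask voxel values back onto the 3-D grid
#'
#' Inverse of [grid_to_voxels()]; out-of-mask voxels are set to `fill`.
#'
#' @param values numeric vector of length `sum(mask)`.
#' @param mask logical 3-D array.
#' @param fill value for out-of-mask voxels (default 0).
#' @return numeric 3-D array with the mask's shape.
#' @export
voxels_to_grid <- function(values, mask, fill = 0) {
  stopifnot(length(values) == sum(mask))
  out <- array(fill, dim = dim(mask))
  out[mask] <- values
  out
}

#' Tissue probability maps
#'
#' Per-voxel probabilities of gray matter, white matter, and cerebrospinal
#' fluid on the decomposition grid, as produced by anatomical segmentation.
#' Values must lie in [0, 1] and sum to at most 1 (within tolerance) at
#' every voxel.
#'
#' @param gm,wm,csf numeric 3-D arrays of identical shape with values in
#'   [0, 1].
#' @return An object of class `tissue_maps`.
#' @seealso [read_tissue_maps()], [tissue_filter()]
#' @export
tissue_maps <- function(gm, wm, csf) {
  dims <- dim(gm)
  if (length(dims) != 3L || !identical(dim(wm), dims) ||
      !identical(dim(csf), dims)) {
    stop("tissue maps must be three 3-D arrays of identical shape",
         call. = FALSE)
  }
  for (nm in c("gm", "wm", "csf")) {
    m <- get(nm)
    if (anyNA(m) || any(m < 0) || any(m > 1)) {
      stop(sprintf("tissue map '%s' has values outside [0, 1]", nm),
           call. = FALSE)
    }
  }
  if (any(gm + wm + csf > 1 + 1e-6)) {
    stop("tissue probabilities sum to more than 1 at some voxel",
         call. = FALSE)
  }
  structure(list(gm = gm, wm = wm, csf = csf, grid_shape = dims),
            class = "tissue_maps")
}

#' Selection configuration
#'
#' All tunable thresholds and seeds of the four-step selection, with the
#' method's defaults.
#'
#' @param skewness_mode compare `"absolute"` (default) or `"signed"`
#'   Pearson coefficients against the threshold in step 1.
#' @param skewness_threshold_override optional fixed threshold TH; when
#'   `NULL` (default) TH is the median of the per-component coefficients.
#' @param k_candidates integer vector of candidate cluster counts for the
#'   step-2 k-means (default `2:9`).
#' @param kmeans_seed integer seed controlling k-means initialisation and
#'   silhouette subsampling (default 0).
#' @param silhouette_subsample maximum number of points scored when
#'   averaging the silhouette index (default 5000).
#' @param tissue_prob_threshold probability above which a voxel counts as
#'   white matter / CSF in step 3 (default 0.9).
#' @param tissue_rule `"either_map"` (default: remove a voxel when WM or
#'   CSF alone reaches the threshold) or `"summed"` (WM + CSF reaches it).
#' @param f1_hz,f2_hz band edges in Hz separating the three spectral bands
#'   (defaults 0.01 and 0.1; resting-state networks live in `[f1, f2)`).
#' @param p2_min minimum fraction of power in `[f1, f2)` (default 0.5).
#' @param p12_min minimum fraction of power below `f2` (default 0.9).
#' @param reject_logic `"or"` (default: reject when either spectral
#'   criterion fails) or `"and"` (reject only when both fail).
#' @param detrend_degree polynomial degree removed from each voxel time
#'   course before averaging (default 1, i.e. linear detrend).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(skewness_mode = c("absolute", "signed"),
                             skewness_threshold_override = NULL,
                             k_candidates = 2:9,
                             kmeans_seed = 0L,
                             silhouette_subsample = 5000L,
                             tissue_prob_threshold = 0.9,
                             tissue_rule = c("either_map", "summed"),
                             f1_hz = 0.01,
                             f2_hz = 0.1,
                             p2_min = 0.5,
                             p12_min = 0.9,
                             reject_logic = c("or", "and"),
                             detrend_degree = 1L) {
  cfg <- structure(list(
    skewness_mode = match.arg(skewness_mode),
    skewness_threshold_override = skewness_threshold_override,
    k_candidates = as.integer(k_candidates),
    kmeans_seed = as.integer(kmeans_seed),
    silhouette_subsample = as.integer(silhouette_subsample),
    tissue_prob_threshold = as.numeric(tissue_prob_threshold),
    tissue_rule = match.arg(tissue_rule),
    f1_hz = as.numeric(f1_hz),
    f2_hz = as.numeric(f2_hz),
    p2_min = as.numeric(p2_min),
    p12_min = as.numeric(p12_min),
    reject_logic = match.arg(reject_logic),
    detrend_degree = as.integer(detrend_degree)
  ), class = "selection_config")
  validate_config(cfg)
  cfg
}

#' Validate a selection configuration
#'
#' @param cfg a [selection_config()].
#' @param tr_seconds optional repetition time; when given, additionally
#'   checks that `f2_hz` lies below the Nyquist frequency `1/(2 TR)`.
#' @return `cfg`, invisibly; errors on any violated constraint.
#' @export
validate_config <- function(cfg, tr_seconds = NULL) {
  stopifnot(inherits(cfg, "selection_config"))
  if (!(cfg$f1_hz > 0 && cfg$f1_hz < cfg$f2_hz)) {
    stop("selection_config: need 0 < f1_hz < f2_hz", call. = FALSE)
  }
  if (!is.null(tr_seconds)) {
    nyq <- 1 / (2 * tr_seconds)
    if (cfg$f2_hz >= nyq) {
      stop(sprintf(
        "selection_config: f2_hz = %g must be below the Nyquist frequency %g Hz (TR = %g s)",
        cfg$f2_hz, nyq, tr_seconds), call. = FALSE)
    }
  }
  for (nm in c("tissue_prob_threshold", "p2_min", "p12_min")) {
    val <- cfg[[nm]]
    if (!is.finite(val) || val <= 0 || val > 1) {
      stop(sprintf("selection_config: %s must be in (0, 1]", nm),
           call. = FALSE)
    }
  }
  if (any(cfg$k_candidates < 2L)) {
    stop("selection_config: all k_candidates must be >= 2", call. = FALSE)
  }
  if (cfg$detrend_degree < 0L) {
    stop("selection_config: detrend_degree must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

# Per-component running record through the pipeline stages.
new_component_state <- function(index, n_voxels) {
  structure(list(
    index = as.integer(index),
    pearson_coefficient = NA_real_,
    retained_voxels = rep(TRUE, n_voxels),
    band_powers = NULL,
    status = "candidate",
    rejection_stage = NA_character_,
    n_voxels_initial = as.integer(n_voxels),
    n_after_clustering = NA_integer_,
    n_after_segmentation = NA_integer_
  ), class = "component_state")
}

# One-way status transition: a rejected component is never resurrected.
reject_state <- function(state, status, stage, reason = NULL) {
  if (state$status != "candidate") {
    stop(sprintf("component %d already finalised as '%s'",
                 state$index, state$status), call. = FALSE)
  }
  state$status <- status
  state$rejection_stage <- stage
  if (!is.null(reason)) {
    message(sprintf("component %d rejected at %s stage: %s",
                    state$index, stage, reason))
  }
  state
}

#' @export
print.component_state <- function(x, ...) {
  cat(sprintf(
    "component %d: status %s, Pearson coefficient %.4g, %d/%d voxels retained\n",
    x$index, x$status, x$pearson_coefficient,
    sum(x$retained_voxels), length(x$retained_voxels)))
  if (!is.null(x$band_powers)) {
    cat(sprintf("  band powers P1 = %.3f, P2 = %.3f, P3 = %.3f\n",
                x$band_powers$p1, x$band_powers$p2, x$band_powers$p3))
  }
  invisible(x)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
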