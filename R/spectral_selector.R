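#' Step 4a: reconstruct a component's mean time course
#'
#' For every retained voxel `m` of component `i`, the voxel's relative
#' time course is `x[, m] = A[, i] * S[i, m]`. Each voxel time course is
#' baseline-corrected (mean removed) and polynomially detrended (degree
#' `cfg$detrend_degree`), then the detrended courses are averaged across
#' voxels.
#'
#' When the retained source values carry mixed signs their weighted
#' average can nearly cancel; the function warns when
#' `|mean(s)| < 1e-3 * mean(|s|)` and proceeds.
#'
#' @param state a `component_state` with at least one retained voxel.
#' @param dec the [ica_decomposition()].
#' @param cfg a [selection_config()].
#' @return numeric vector of length `N` (time points).
#' @export
reconstruct_mean_timecourse <- function(state, dec, cfg = selection_config()) {
  idx <- which(state$retained_voxels)
  if (!length(idx)) {
    stop(sprintf("component %d has no retained voxels", state$index),
         call. = FALSE)
  }
  s <- dec$sources[state$index, idx]
  if (mean(abs(s)) > 0 && abs(mean(s)) < 1e-3 * mean(abs(s))) {
    warning(sprintf(
      "component %d: retained source values nearly cancel (mixed signs); mean time course may be degenerate",
      state$index), call. = FALSE)
  }
  a <- dec$mixing[, state$index]
  x <- outer(a, s)                                  # N x m voxel courses
  x <- sweep(x, 2L, colMeans(x))                    # baseline correction
  if (cfg$detrend_degree > 0L) {
    tt <- seq_len(nrow(x))
    basis <- cbind(1, stats::poly(tt, degree = cfg$detrend_degree))
    x <- qr.resid(qr(basis), x)
  }
  rowMeans(x)
}

#' Step 4b: periodogram band-power fractions
#'
#' Computes the raw (unwindowed) periodogram of the demeaned series and
#' partitions its frequency bins — the DC bin excluded — into three bands:
#' `P1` below `f1`, `P2` in `[f1, f2)` (where resting-state fluctuations
#' concentrate), and `P3` from `f2` up to Nyquist. A bin belongs to a band
#' by its centre frequency `k / (N * TR)`. Each band's power is divided by
#' the total power over all non-DC bins, so `P1 + P2 + P3 = 1`.
#'
#' @param timecourse numeric vector, length >= 8.
#' @param tr_seconds sampling interval in seconds.
#' @param cfg a [selection_config()] supplying `f1_hz`, `f2_hz`.
#' @return An object of class `band_powers` with fields `p1`, `p2`, `p3`,
#'   `nyquist_hz`, `n_frequencies`.
#' @export
band_powers <- function(timecourse, tr_seconds, cfg = selection_config()) {
  x <- as.numeric(timecourse)
  n <- length(x)
  if (n < 8L) stop("band_powers needs at least 8 time points", call. = FALSE)
  if (!is.finite(tr_seconds) || tr_seconds <= 0) {
    stop("tr_seconds must be positive", call. = FALSE)
  }
  nyquist <- 1 / (2 * tr_seconds)
  if (cfg$f2_hz >= nyquist) {
    stop(sprintf("f2_hz = %g is not below the Nyquist frequency %g Hz",
                 cfg$f2_hz, nyquist), call. = FALSE)
  }
  x <- x - mean(x)
  pgram <- Mod(stats::fft(x))^2 / n
  kmax <- n %/% 2L
  freqs <- seq_len(kmax) / (n * tr_seconds)
  power <- pgram[seq_len(kmax) + 1L]                # DC bin excluded
  total <- sum(power)
  if (total <= 0) {
    stop("zero total power: spectrum undefined", call. = FALSE)
  }
  structure(list(
    p1 = sum(power[freqs < cfg$f1_hz]) / total,
    p2 = sum(power[freqs >= cfg$f1_hz & freqs < cfg$f2_hz]) / total,
    p3 = sum(power[freqs >= cfg$f2_hz]) / total,
    nyquist_hz = nyquist,
    n_frequencies = kmax
  ), class = "band_powers")
}

# The rejection rule on band fractions; OR-logic (the default) rejects a
# component when either criterion fails, AND-logic only when both do.
spectral_reject <- function(p1, p2, cfg) {
  low_p2 <- p2 < cfg$p2_min
  low_p12 <- (p1 + p2) < cfg$p12_min
  if (cfg$reject_logic == "or") low_p2 || low_p12 else low_p2 && low_p12
}

#' Step 4: spectral band-power filtering
#'
#' For every still-candidate component, reconstructs the mean time course
#' over its retained voxels, computes the band-power fractions, and rejects
#' the component when its power profile is not dominated by low-frequency
#' fluctuation: by default when `P2 < 50%` or `P1 + P2 < 90%`. Survivors
#' get status `selected`. Components with an undefined (zero-power)
#' spectrum are demoted to `rejected_spectral` with a logged reason.
#'
#' @param states list of `component_state` processed through steps 1-3.
#' @param dec the [ica_decomposition()].
#' @param cfg a [selection_config()].
#' @return the updated list of states (attributes preserved).
#' @export
spectral_filter <- function(states, dec, cfg = selection_config()) {
  out <- lapply(states, function(state) {
    if (state$status != "candidate") return(state)
    bp <- tryCatch({
      tc <- reconstruct_mean_timecourse(state, dec, cfg)
      band_powers(tc, dec$tr_seconds, cfg)
    }, error = function(e) e)
    if (inherits(bp, "error")) {
      return(reject_state(state, "rejected_spectral", "spectral",
                          conditionMessage(bp)))
    }
    state$band_powers <- bp
    if (spectral_reject(bp$p1, bp$p2, cfg)) {
      state <- reject_state(state, "rejected_spectral", "spectral")
    } else {
      state$status <- "selected"
    }
    state
  })
  attributes(out) <- attributes(states)
  out
}
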