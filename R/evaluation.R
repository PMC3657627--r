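#' Confusion counts against a reference labelling
#'
#' Compares the automatically selected component indices with a reference
#' set (e.g. expert-labelled resting-state networks): true positives are
#' selected components that are in the reference, false positives selected
#' but not in the reference, false negatives missed reference components,
#' and true negatives components correctly left unselected.
#'
#' @param selected integer vector of selected component indices (1-based).
#' @param reference integer vector of reference component indices.
#' @param total total number of components in the decomposition.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `fn`, `tn` summing to `total`.
#' @export
confusion <- function(selected, reference, total) {
  selected <- unique(as.integer(selected))
  reference <- unique(as.integer(reference))
  total <- as.integer(total)
  all_idx <- c(selected, reference)
  if (length(all_idx) && (any(all_idx < 1L) || any(all_idx > total))) {
    stop(sprintf("component indices must lie in [1, %d]", total),
         call. = FALSE)
  }
  tp <- length(intersect(selected, reference))
  fp <- length(setdiff(selected, reference))
  fn <- length(setdiff(reference, selected))
  structure(list(tp = tp, fp = fp, fn = fn, tn = total - tp - fp - fn),
            class = "confusion_counts")
}

#' Accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`: the fraction of components whose
#' automatic decision (selected or rejected) agrees with the reference.
#'
#' @param c a `confusion_counts` object (or a list with fields
#'   `tp`, `fp`, `fn`, `tn`).
#' @return value in [0, 1].
#' @export
accuracy <- function(c) {
  total <- c$tp + c$fp + c$fn + c$tn
  if (total <= 0) stop("accuracy undefined for zero total", call. = FALSE)
  (c$tp + c$tn) / total
}

#' Precision
#'
#' `TP / (TP + FP)`: the fraction of selected components that the
#' reference confirms as resting-state networks.
#'
#' @inheritParams accuracy
#' @return value in [0, 1]; errors when nothing was selected
#'   (`TP + FP == 0`).
#' @export
precision <- function(c) {
  if (c$tp + c$fp <= 0) {
    stop("precision undefined: no components selected (TP + FP = 0)",
         call. = FALSE)
  }
  c$tp / (c$tp + c$fp)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP %d, FP %d, FN %d, TN %d (total %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Match selected components across two sessions
#'
#' Greedy one-to-one matching of component spatial maps by descending
#' Pearson spatial correlation: repeatedly pairs the most-correlated
#' unmatched components, stopping when no remaining pair reaches
#' `r_threshold`. An objective surrogate for expert reproducibility
#' judgement; it does not reproduce expert-labelled session comparisons.
#'
#' @param maps_a,maps_b numeric matrices, components x voxels, on the same
#'   voxel grid (equal column counts). Typically the retained-voxel
#'   filtered source rows of the selected components of each session.
#' @param r_threshold minimum correlation for a pair to count as matched
#'   (default 0.4).
#' @return data frame with columns `index_a`, `index_b`, `correlation`,
#'   one row per matched pair, in matching order.
#' @export
match_sessions <- function(maps_a, maps_b, r_threshold = 0.4) {
  maps_a <- as.matrix(maps_a)
  maps_b <- as.matrix(maps_b)
  if (ncol(maps_a) != ncol(maps_b)) {
    stop(sprintf(
      "voxel grids differ: maps_a has %d voxels, maps_b has %d",
      ncol(maps_a), ncol(maps_b)), call. = FALSE)
  }
  empty <- data.frame(index_a = integer(0), index_b = integer(0),
                      correlation = numeric(0))
  if (nrow(maps_a) == 0L || nrow(maps_b) == 0L) return(empty)
  r <- suppressWarnings(stats::cor(t(maps_a), t(maps_b)))
  r <- matrix(r, nrow = nrow(maps_a))
  r[!is.finite(r)] <- -Inf                 # zero-variance maps never match
  pairs <- empty
  repeat {
    best <- which.max(r)
    if (!length(best) || r[best] < r_threshold) break
    i <- (best - 1L) %% nrow(r) + 1L
    j <- (best - 1L) %/% nrow(r) + 1L
    pairs <- rbind(pairs, data.frame(index_a = i, index_b = j,
                                     correlation = r[best]))
    r[i, ] <- -Inf
    r[, j] <- -Inf
  }
  pairs
}
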