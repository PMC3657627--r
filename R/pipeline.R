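#' Run the four-step component selection pipeline
#'
#' Applies, in order: (1) skewness-based component rejection, (2) k-means
#' voxel filtering with silhouette-chosen k, (3) tissue-probability voxel
#' masking, (4) spectral band-power rejection. Steps 1 and 4 act on whole
#' components; steps 2 and 3 zero out voxels of the surviving components.
#' Every component's fate and intermediate statistics are recorded; a
#' failure on a single component (degenerate values, undefined spectrum)
#' demotes that component rather than aborting the run. The result is
#' deterministic given the configuration's seeds.
#'
#' @param dec an [ica_decomposition()].
#' @param tissue a [tissue_maps()] on the same grid.
#' @param cfg a [selection_config()].
#' @return An object of class `pipeline_result` with fields `states` (one
#'   `component_state` per component), `report` (a `selection_report`),
#'   `selected_indices`, and `counts` (named vector `K`, `I`, `J`: total
#'   components, survivors of step 1, finally selected).
#' @export
run_pipeline <- function(dec, tissue, cfg = selection_config()) {
  violations <- validate_decomposition(dec)
  if (length(violations)) {
    stop("invalid decomposition:\n  - ",
         paste(violations, collapse = "\n  - "), call. = FALSE)
  }
  stopifnot(inherits(tissue, "tissue_maps"))
  if (!identical(tissue$grid_shape, dec$grid_shape)) {
    stop(sprintf("tissue grid %s does not match decomposition grid %s",
                 paste(tissue$grid_shape, collapse = "x"),
                 paste(dec$grid_shape, collapse = "x")), call. = FALSE)
  }
  validate_config(cfg, dec$tr_seconds)

  states <- skewness_filter(dec, cfg)
  th <- attr(states, "threshold")
  for (i in seq_along(states)) {
    if (states[[i]]$status != "candidate") next
    states[[i]] <- cluster_filter(states[[i]], dec, cfg)
    if (states[[i]]$status != "candidate") next
    states[[i]] <- tissue_filter(states[[i]], tissue, dec, cfg)
  }
  states <- spectral_filter(states, dec, cfg)

  statuses <- vapply(states, function(s) s$status, character(1))
  K <- length(states)
  I <- sum(statuses != "rejected_skewness")
  selected <- which(statuses == "selected")
  J <- length(selected)
  report <- build_report(states, cfg, th, c(K = K, I = I, J = J))
  structure(list(states = states, report = report,
                 selected_indices = selected,
                 counts = c(K = K, I = I, J = J)),
            class = "pipeline_result")
}

build_report <- function(states, cfg, threshold, counts) {
  comp_row <- function(s) {
    bp <- s$band_powers
    data.frame(
      index = s$index,
      pearson_coefficient = s$pearson_coefficient,
      n_voxels_initial = s$n_voxels_initial,
      n_after_clustering = s$n_after_clustering,
      n_after_segmentation = s$n_after_segmentation,
      chosen_k = if (is.null(s$chosen_k)) NA_integer_ else s$chosen_k,
      p1 = if (is.null(bp)) NA_real_ else bp$p1,
      p2 = if (is.null(bp)) NA_real_ else bp$p2,
      p3 = if (is.null(bp)) NA_real_ else bp$p3,
      status = s$status,
      rejection_stage = s$rejection_stage,
      stringsAsFactors = FALSE)
  }
  components <- if (length(states)) {
    do.call(rbind, c(lapply(states, comp_row),
                     list(make.row.names = FALSE)))
  } else {
    comp_row(new_component_state(1L, 0L))[0, ]
  }
  structure(list(
    config = cfg,
    summary = list(K = unname(counts["K"]), I = unname(counts["I"]),
                   J = unname(counts["J"]), threshold = threshold),
    components = components
  ), class = "selection_report")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "component selection: K = %d components, I = %d after skewness filter, J = %d selected\n",
    x$counts["K"], x$counts["I"], x$counts["J"]))
  cat(sprintf("  skewness threshold TH = %.4g\n", x$report$summary$threshold))
  if (length(x$selected_indices)) {
    cat("  selected components:", paste(x$selected_indices, collapse = ", "),
        "\n")
  } else {
    cat("  no components selected\n")
  }
  invisible(x)
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("selection report: K = %d, I = %d, J = %d (TH = %.4g)\n",
              x$summary$K, x$summary$I, x$summary$J, x$summary$threshold))
  print(x$components)
  invisible(x)
}
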