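# NIfTI readers can drop trailing singleton dimensions; restore a fixed
# dimensionality (3 for volumes, 4 for component stacks).
pad_dims <- function(arr, ndim) {
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  while (length(d) > ndim && d[length(d)] == 1L) d <- d[-length(d)]
  while (length(d) < ndim) d <- c(d, 1L)
  dim(arr) <- d
  arr
}

# Parse a whitespace-delimited mixing matrix ("melodic_mix" dialect):
# one time point per row, one component per column, no header.
read_mix_matrix <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (!length(lines)) stop("mixing matrix file is empty", call. = FALSE)
  rows <- lapply(seq_along(lines), function(i) {
    tokens <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tokens))
    if (anyNA(vals)) {
      bad <- tokens[which(is.na(vals))[1]]
      stop(sprintf("non-numeric token '%s' in mixing matrix at line %d",
                   bad, line_no[i]), call. = FALSE)
    }
    vals
  })
  widths <- unique(lengths(rows))
  if (length(widths) != 1L) {
    stop(sprintf("ragged mixing matrix: rows have %s columns",
                 paste(sort(widths), collapse = ", ")), call. = FALSE)
  }
  matrix(unlist(rows), nrow = length(rows), byrow = TRUE)
}

write_mix_matrix <- function(mixing, path) {
  lines <- apply(mixing, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(lines, path)
}

#' Read a decomposition from MELODIC-style files
#'
#' Loads component spatial maps from a 4-D NIfTI volume (component as the
#' 4th dimension), the mixing matrix from a whitespace-delimited text file
#' (one time point per row), and the brain mask from a 3-D NIfTI volume,
#' and assembles a validated [ica_decomposition()]. Source rows are the
#' in-mask values of each 3-D component map in the package's fixed
#' column-major voxel order.
#'
#' @param maps_path path to the 4-D NIfTI of spatial maps.
#' @param mix_path path to the mixing-matrix text file.
#' @param mask_path path to the 3-D NIfTI brain mask (nonzero = in mask).
#' @param tr_seconds repetition time in seconds.
#' @return an [ica_decomposition()].
#' @export
read_decomposition <- function(maps_path, mix_path, mask_path, tr_seconds) {
  for (p in c(maps_path, mix_path, mask_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  maps <- as.array(RNifti::readNifti(maps_path))
  if (length(dim(maps)) > 4L) {
    stop(sprintf("component maps must be 4-D, got %d-D",
                 length(dim(maps))), call. = FALSE)
  }
  maps <- pad_dims(maps, 4L)
  mask_arr <- pad_dims(as.array(RNifti::readNifti(mask_path)), 3L)
  if (!identical(dim(mask_arr), dim(maps)[1:3])) {
    stop(sprintf("mask grid %s does not match maps grid %s",
                 paste(dim(mask_arr), collapse = "x"),
                 paste(dim(maps)[1:3], collapse = "x")), call. = FALSE)
  }
  mask <- array(mask_arr > 0.5, dim = dim(mask_arr))
  if (!any(mask)) stop("mask has no in-brain voxels", call. = FALSE)
  mixing <- read_mix_matrix(mix_path)
  K <- dim(maps)[4]
  if (ncol(mixing) != K) {
    stop(sprintf(
      "component count mismatch: maps have %d components but mixing matrix has %d columns",
      K, ncol(mixing)), call. = FALSE)
  }
  sources <- matrix(0, nrow = K, ncol = sum(mask))
  for (i in seq_len(K)) sources[i, ] <- maps[, , , i][mask]
  ica_decomposition(mixing, sources, mask, tr_seconds)
}

#' Write a decomposition to MELODIC-style files
#'
#' Inverse of [read_decomposition()]: writes the spatial maps as a 4-D
#' NIfTI (out-of-mask voxels 0), the mixing matrix as whitespace-delimited
#' text with full double precision, and the mask as a 3-D NIfTI.
#'
#' @param dec an [ica_decomposition()].
#' @param maps_path,mix_path,mask_path output paths.
#' @return `dec`, invisibly.
#' @export
write_decomposition <- function(dec, maps_path, mix_path, mask_path) {
  K <- ncol(dec$mixing)
  maps <- array(0, dim = c(dec$grid_shape, K))
  for (i in seq_len(K)) {
    maps[, , , i] <- voxels_to_grid(dec$sources[i, ], dec$mask)
  }
  RNifti::writeNifti(maps, maps_path, datatype = "double")
  RNifti::writeNifti(array(as.integer(dec$mask), dim = dec$grid_shape),
                     mask_path, datatype = "uint8")
  write_mix_matrix(dec$mixing, mix_path)
  invisible(dec)
}

#' Read tissue probability maps
#'
#' Loads gray-matter, white-matter, and CSF probability volumes, checks
#' that they share the decomposition grid, and clips values to [0, 1]
#' (with a warning when any input value falls outside by more than 1e-6,
#' as can happen with interpolated segmentations).
#'
#' @param gm_path,wm_path,csf_path paths to 3-D NIfTI probability maps.
#' @param dec the [ica_decomposition()] defining the grid.
#' @return a [tissue_maps()].
#' @export
read_tissue_maps <- function(gm_path, wm_path, csf_path, dec) {
  load_one <- function(path, name) {
    arr <- pad_dims(as.array(RNifti::readNifti(path)), 3L)
    if (!identical(dim(arr), dec$grid_shape)) {
      stop(sprintf("%s grid %s does not match decomposition grid %s",
                   name, paste(dim(arr), collapse = "x"),
                   paste(dec$grid_shape, collapse = "x")), call. = FALSE)
    }
    if (any(arr < -1e-6) || any(arr > 1 + 1e-6)) {
      warning(sprintf("%s map has values outside [0, 1]; clipping", name),
              call. = FALSE)
    }
    array(pmin(pmax(arr, 0), 1), dim = dec$grid_shape)
  }
  tissue_maps(load_one(gm_path, "gray-matter"),
              load_one(wm_path, "white-matter"),
              load_one(csf_path, "CSF"))
}

#' Write a selection report
#'
#' Serialises a `selection_report` (see [run_pipeline()]) either as JSON
#' (full report: per-component records, configuration echo, and the
#' K / I / J summary; round-trips through [read_report()]) or as TSV (the
#' per-component table only: one header row plus K data rows).
#'
#' @param report a `selection_report`.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "selection_report"))
  if (format == "tsv") {
    utils::write.table(report$components, path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    payload <- list(
      config = Filter(Negate(is.null), unclass(report$config)),
      summary = report$summary,
      components = report$components
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", dataframe = "rows")
  }
  invisible(path)
}

#' Read a JSON selection report
#'
#' @param path path to a JSON file written by [write_report()].
#' @return a `selection_report`.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_args <- payload$config
  cfg_args$k_candidates <- as.integer(unlist(cfg_args$k_candidates))
  cfg <- do.call(selection_config, cfg_args)
  comps <- as.data.frame(payload$components)
  int_cols <- c("index", "n_voxels_initial", "n_after_clustering",
                "n_after_segmentation", "chosen_k")
  num_cols <- c("pearson_coefficient", "p1", "p2", "p3")
  chr_cols <- c("status", "rejection_stage")
  if (nrow(comps)) {
    for (nm in intersect(int_cols, names(comps))) {
      comps[[nm]] <- as.integer(comps[[nm]])
    }
    for (nm in intersect(num_cols, names(comps))) {
      comps[[nm]] <- as.numeric(comps[[nm]])
    }
    for (nm in intersect(chr_cols, names(comps))) {
      comps[[nm]] <- as.character(comps[[nm]])
    }
  }
  structure(list(
    config = cfg,
    summary = list(K = as.integer(payload$summary$K),
                   I = as.integer(payload$summary$I),
                   J = as.integer(payload$summary$J),
                   threshold = as.numeric(payload$summary$threshold)),
    components = comps
  ), class = "selection_report")
}

#' Write the selected, voxel-filtered component maps
#'
#' Writes a 4-D NIfTI containing only the selected components, with
#' non-retained voxels set to 0 — the cleaned spatial maps the pipeline
#' would hand to downstream analysis.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param dec the [ica_decomposition()] the result was computed from.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selected_maps <- function(result, dec, path) {
  sel <- result$selected_indices
  arr <- array(0, dim = c(dec$grid_shape, max(length(sel), 1L)))
  for (j in seq_along(sel)) {
    st <- result$states[[sel[j]]]
    vals <- dec$sources[sel[j], ] * st$retained_voxels
    arr[, , , j] <- voxels_to_grid(vals, dec$mask)
  }
  RNifti::writeNifti(arr, path, datatype = "double")
  invisible(path)
}
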