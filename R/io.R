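# File-format adapters: NIfTI-1 volumes via RNifti, participant/regional
# tables as TSV, band and label metadata as YAML/JSON.

#' Read a 4D BOLD NIfTI file as a time-series grid
#'
#' Flattens the spatial grid to voxels x time. The repetition time is taken
#' from the file header (`pixdim[4]`) unless overridden.
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param tr Optional TR override in seconds.
#' @return A [bold_ts()]; spatial dimensions kept in attribute `dim3`.
#' @export
read_bold_nifti <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D BOLD volume, got dims ", length(d))
  if (is.null(tr)) {
    tr <- RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0) {
      stop("file header has no usable TR; pass 'tr' explicitly")
    }
  }
  values <- matrix(as.numeric(img), nrow = prod(d[1:3]), ncol = d[4])
  out <- bold_ts(values, tr)
  attr(out, "dim3") <- d[1:3]
  out
}

#' Write a voxel map as a 3D NIfTI file
#'
#' @param values Numeric vector, one value per voxel (`NA` allowed).
#' @param dim3 Integer vector of length 3, the spatial grid.
#' @param path Output path.
#' @param voxel_size_mm Isotropic voxel size recorded in the header.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(values, dim3, path, voxel_size_mm = 2.4) {
  if (length(values) != prod(dim3)) stop("value count does not match dim3")
  img <- RNifti::asNifti(array(as.numeric(values), dim = dim3))
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a time-series grid as a 4D NIfTI file
#'
#' @param ts A [bold_ts()].
#' @param dim3 Spatial dimensions (must multiply to the voxel count).
#' @param path Output path.
#' @param voxel_size_mm Isotropic voxel size recorded in the header.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(ts, dim3, path, voxel_size_mm = 2.4) {
  stopifnot(inherits(ts, "bold_ts"))
  if (nrow(ts$values) != prod(dim3)) stop("voxel count does not match dim3")
  arr <- array(as.vector(ts$values), dim = c(dim3, ts$n_timepoints))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(voxel_size_mm, 3), ts$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an ROI label volume with its JSON sidecar
#'
#' The sidecar maps labels to region names and states the reference label:
#' `{"labels": {"1": "frontal_gm", "2": "medulla"}, "reference": 1}`.
#'
#' @param label_path Integer NIfTI-1 label volume (0 = background).
#' @param sidecar_path JSON sidecar file.
#' @return A [roi_set()].
#' @export
read_roi_nifti <- function(label_path, sidecar_path) {
  img <- RNifti::readNifti(label_path)
  meta <- jsonlite::read_json(sidecar_path)
  labels <- as.integer(round(as.numeric(img)))
  name_map <- stats::setNames(
    vapply(meta$labels, as.character, character(1)),
    names(meta$labels)
  )
  roi_set(labels, name_map, reference_label = as.integer(meta$reference))
}

#' Write an ROI set as a NIfTI label volume plus JSON sidecar
#'
#' @param rois A [roi_set()].
#' @param dim3 Spatial dimensions.
#' @param label_path,sidecar_path Output paths.
#' @param voxel_size_mm Isotropic voxel size recorded in the header.
#' @return `label_path`, invisibly.
#' @export
write_roi_nifti <- function(rois, dim3, label_path, sidecar_path,
                            voxel_size_mm = 2.4) {
  stopifnot(inherits(rois, "roi_set"))
  write_map_nifti(rois$labels, dim3, label_path, voxel_size_mm)
  jsonlite::write_json(
    list(labels = as.list(rois$names), reference = rois$reference_label),
    sidecar_path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(label_path)
}

#' Read or write a participant table as TSV
#'
#' Columns: `id`, `group`, `age`, `sex`, `bmi`, `systolic`, `diastolic`
#' (plus any added by [fit_propensity()] / [match_cohort()]).
#'
#' @param path TSV file path.
#' @return `read_participants_tsv`: the data.frame.
#' @export
read_participants_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_participants(tab)
  tab
}

#' @rdname read_participants_tsv
#' @param table Participant data.frame.
#' @export
write_participants_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a frequency band from a YAML config
#'
#' Expects `band: {low: 0.0, high: 0.1164}` (Hz).
#'
#' @param path YAML file path.
#' @return A [band_spec()].
#' @export
read_band_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$band) || is.null(y$band$low) || is.null(y$band$high)) {
    stop("YAML must contain band: {low: ..., high: ...}")
  }
  band_spec(y$band$low, y$band$high)
}
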