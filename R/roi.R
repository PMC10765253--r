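#' Region-of-interest label set
#'
#' Integer labels per voxel (0 = background), a label-to-name map, and the
#' label of the reference region used for z-score standardisation (frontal
#' grey matter in the hypertension study design). Build from a NIfTI label
#' volume plus JSON sidecar with [read_roi_nifti()], or synthesise with
#' [synthetic_rois()].
#'
#' @param labels Integer vector (or array, flattened), one label per voxel.
#' @param names Named character vector mapping label id (as name) to region
#'   name, e.g. `c("1" = "frontal_gm", "2" = "medulla")`. Every named label
#'   must occur in `labels`.
#' @param reference_label Integer label of the standardisation region; must
#'   cover at least 2 voxels.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(labels, names, reference_label) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("NA labels in ROI volume")
  if (is.null(base::names(names)) || any(base::names(names) == "")) {
    stop("'names' must be a fully named character vector (label id -> region name)")
  }
  ids <- as.integer(base::names(names))
  missing_ids <- ids[!ids %in% labels]
  if (length(missing_ids) > 0L) {
    stop("named labels absent from volume: ", paste(missing_ids, collapse = ", "))
  }
  if (anyDuplicated(unname(names))) stop("duplicate region names")
  reference_label <- as.integer(reference_label)
  if (!reference_label %in% ids) {
    stop("reference label ", reference_label, " is not a named label")
  }
  if (sum(labels == reference_label) < 2L) {
    stop("reference region must cover at least 2 voxels")
  }
  nm <- as.character(names)
  base::names(nm) <- base::names(names)
  structure(
    list(labels = labels, names = nm, reference_label = reference_label),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf(
    "ROI set: %d voxels, %d named regions, reference = %s (label %d)\n",
    length(x$labels), length(x$names),
    x$names[as.character(x$reference_label)], x$reference_label
  ))
  invisible(x)
}

#' Standardise an amplitude map against the reference region
#'
#' Converts a voxelwise fALFF map to z-scores: the mean over the reference
#' region's voxels is subtracted and the result divided by the reference
#' region's standard deviation (sample, n-1). Standardisation is within
#' participant, each map against its own reference statistics, which
#' removes participant-level global scaling before group comparison.
#' Undefined (`NA`) fALFF voxels stay `NA`.
#'
#' @param map An [falff()] / [alff()] `amplitude_map` over the same voxel
#'   grid as `rois`.
#' @param rois A [roi_set()].
#' @return An object of class `zscore_map`: list with `values` and the
#'   standardisation constants `reference_mean`, `reference_sd`.
#' @export
zscore_against_reference <- function(map, rois) {
  stopifnot(inherits(map, "amplitude_map"), inherits(rois, "roi_set"))
  if (length(map$values) != length(rois$labels)) {
    stop("amplitude map and ROI volume have different voxel counts")
  }
  ref <- map$values[rois$labels == rois$reference_label]
  ref <- ref[!is.na(ref)]
  if (length(ref) < 2L) stop("reference region has fewer than 2 defined voxels")
  m <- mean(ref)
  s <- stats::sd(ref)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate reference region: zero standard deviation")
  }
  structure(
    list(values = (map$values - m) / s, reference_mean = m, reference_sd = s),
    class = "zscore_map"
  )
}

#' @export
print.zscore_map <- function(x, ...) {
  cat(sprintf(
    "fALFF z-score map: %d voxels, reference mean %.4g, sd %.4g\n",
    length(x$values), x$reference_mean, x$reference_sd
  ))
  invisible(x)
}

#' Regional mean z-scores
#'
#' Averages a z-score map over every named region, one row per region.
#' Missing voxels are excluded from the mean; a region whose voxels are all
#' missing keeps its row with `mean_z = NA` and `n_used = 0` rather than
#' being dropped.
#'
#' @param z A [zscore_against_reference()] result.
#' @param rois A [roi_set()].
#' @param participant_id Identifier copied into every row.
#' @return A data.frame with columns `participant_id`, `region`, `mean_z`,
#'   `n_voxels`, `n_used`.
#' @export
regional_means <- function(z, rois, participant_id) {
  stopifnot(inherits(z, "zscore_map"), inherits(rois, "roi_set"))
  ids <- as.integer(names(rois$names))
  rows <- lapply(seq_along(ids), function(i) {
    v <- z$values[rois$labels == ids[i]]
    ok <- !is.na(v)
    data.frame(
      participant_id = participant_id,
      region = unname(rois$names[i]),
      mean_z = if (any(ok)) mean(v[ok]) else NA_real_,
      n_voxels = length(v),
      n_used = sum(ok),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (any(out$n_used == 0L)) {
    warning("region(s) with no defined voxels: ",
            paste(out$region[out$n_used == 0L], collapse = ", "))
  }
  out
}
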