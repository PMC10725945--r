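# ROI-to-atlas overlap quantification and centroid-to-region labeling.

#' Overlap between an ROI and one atlas tract
#'
#' Counts shared voxels and reports the overlap as a fraction of the tract
#' volume. The *reported* fraction is floor-truncated to 2 decimals
#' (`floor(100 * overlap / structure) / 100`), matching the convention of
#' published overlap tables; the exact value is retained alongside.
#'
#' @param roi a `roi_mask` (or any object with binary `$voxels` and
#'   `$grid`).
#' @param tract an `atlas_tract`.
#' @return one-row data.frame: `tract_name`, `overlap_voxels`,
#'   `structure_voxels`, `overlap_fraction` (truncated),
#'   `overlap_fraction_exact`.
#' @export
tract_overlap <- function(roi, tract) {
  if (!grid_equal(roi$grid, tract$grid))
    stop_grid_mismatch(tract$grid, roi$grid, tract$name)
  ov <- sum(roi$voxels != 0L & tract$mask != 0L)
  st <- sum(tract$mask != 0L)
  data.frame(tract_name = tract$name,
             overlap_voxels = ov,
             structure_voxels = st,
             overlap_fraction = truncate_fraction(ov, st),
             overlap_fraction_exact = ov / st,
             stringsAsFactors = FALSE)
}

truncate_fraction <- function(overlap, structure) {
  # floor to 2 decimals in exact integer arithmetic (voxel counts are
  # integers, so (100 * overlap) %/% structure avoids float ulp surprises)
  ((100 * as.numeric(overlap)) %/% as.numeric(structure)) / 100
}

#' Overlap table between an ROI and a whole atlas
#'
#' One row per tract with at least `min_overlap` shared voxels, ordered by
#' tract volume descending (ties by name) to match the layout of published
#' structure-impairment tables.
#'
#' @param roi a `roi_mask`.
#' @param atlas named list of `atlas_tract` objects ([generate_atlas()],
#'   [read_atlas_dir()]).
#' @param min_overlap minimum shared voxel count to list a tract (0 lists
#'   all).
#' @param roi_label label column value; defaults to the ROI's own label.
#' @return data.frame with columns roi_label, tract_name, overlap_voxels,
#'   structure_voxels, overlap_fraction, overlap_fraction_exact.
#' @export
overlap_table <- function(roi, atlas, min_overlap = 1L, roi_label = NULL) {
  if (is.null(roi_label))
    roi_label <- if (!is.null(roi$label)) roi$label else "ROI"
  rows <- lapply(atlas, function(tr) tract_overlap(roi, tr))
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0L)
    return(data.frame(roi_label = character(0), tract_name = character(0),
                      overlap_voxels = integer(0), structure_voxels = integer(0),
                      overlap_fraction = numeric(0),
                      overlap_fraction_exact = numeric(0)))
  tab <- tab[tab$overlap_voxels >= min_overlap, , drop = FALSE]
  tab <- tab[order(-tab$structure_voxels, tab$tract_name), , drop = FALSE]
  rownames(tab) <- NULL
  cbind(roi_label = rep(roi_label, nrow(tab)), tab)
}

#' Region label at a world point
#'
#' Looks up the integer label of the voxel containing a world-mm point in a
#' labeled atlas volume and translates it through a name map. Points on a
#' voxel face belong to the higher-index voxel (floor rule); label 0 is
#' `"background"`. Used to attribute lesion centroids to named regions
#' (e.g. lobes).
#'
#' @param point_mm numeric length-3 world coordinate.
#' @param label_volume 3D integer array of region labels.
#' @param grid the [reference_grid()] of `label_volume`.
#' @param name_map named character vector or list mapping label number (as
#'   name) to region name, e.g. `c("1" = "frontal")`.
#' @return region name (character scalar).
#' @export
label_at_point <- function(point_mm, label_volume, grid, name_map) {
  idx <- world_to_voxel(grid, point_mm)  # errors when outside the grid
  lab <- label_volume[idx[1], idx[2], idx[3]]
  if (lab == 0) return("background")
  nm <- name_map[[as.character(lab)]]
  if (is.null(nm) || is.na(nm))
    stop("label ", lab, " has no entry in the name map", call. = FALSE)
  nm
}

#' Write an overlap table as TSV
#' @param tab result of [overlap_table()].
#' @param path output path.
#' @export
write_overlap_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
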