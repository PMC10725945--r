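#' Construct a lesion mask
#'
#' A lesion mask is one patient's binary tumor segmentation on the cohort
#' reference grid.
#'
#' @param patient_id character scalar.
#' @param grid a [reference_grid()].
#' @param voxels 3D array; coerced to 0/1 integers (any non-zero is
#'   foreground). Shape must match the grid.
#' @return object of class `lesion_mask`.
#' @export
lesion_mask <- function(patient_id, grid, voxels) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L,
            inherits(grid, "reference_grid"))
  if (length(dim(voxels)) != 3L ||
      !identical(as.integer(dim(voxels)), grid$shape))
    stop("`voxels` must be a 3D array matching the grid shape", call. = FALSE)
  v <- array(as.integer(voxels != 0), dim = grid$shape)
  structure(list(patient_id = patient_id, grid = grid, voxels = v),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> patient %s: %d foreground voxels on %s\n",
              x$patient_id, sum(x$voxels), format_grid(x$grid)))
  invisible(x)
}

#' Read a binary lesion mask from a NIfTI file
#'
#' Values are binarized at > 0.5 after reading (robust to interpolation
#' artifacts from prior resampling). The file's grid must match
#' `expected_grid` (shape exactly; voxel size and origin within 1e-4 mm),
#' otherwise a hard error names both grids.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param expected_grid the cohort [reference_grid()].
#' @param patient_id patient identifier; defaults to the file name stem.
#' @return a [lesion_mask()].
#' @export
read_mask <- function(path, expected_grid, patient_id = NULL) {
  vol <- read_nifti_volume(path)
  if (!grid_equal(vol$grid, expected_grid))
    stop_grid_mismatch(vol$grid, expected_grid, what = path)
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  lesion_mask(patient_id, expected_grid, vol$data > 0.5)
}

#' Write a lesion mask to NIfTI
#' @param mask a [lesion_mask()].
#' @param path output path (`.nii` / `.nii.gz`).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  write_nifti_volume(mask$voxels, mask$grid, path, datatype = "uint8")
}

#' Lesion volume in cm^3
#'
#' Foreground voxel count times voxel volume, converted from mm^3 to cm^3.
#' An empty mask yields 0 with a warning.
#'
#' @param mask a [lesion_mask()].
#' @return volume in cm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  n <- sum(mask$voxels)
  if (n == 0L) warning("empty mask for patient ", mask$patient_id,
                       ": volume 0", call. = FALSE)
  n * voxel_volume_mm3(mask$grid) / 1000
}

#' Lesion centroid in world coordinates (mm)
#'
#' Mean of the world coordinates of all foreground voxel centers, one value
#' per axis.
#'
#' @param mask a non-empty [lesion_mask()].
#' @return numeric length-3 centroid in mm.
#' @export
mask_centroid <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  idx <- which(mask$voxels != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("empty mask for patient ", mask$patient_id,
         ": centroid undefined", call. = FALSE)
  colMeans(voxel_to_world(mask$grid, idx))
}

#' Relative volume discrepancy between two raters' masks
#'
#' `|vol(a) - vol(b)| / mean(vol(a), vol(b))` — symmetric in its arguments.
#' Used to decide whether two manual segmentations agree well enough to be
#' merged or must be adjudicated.
#'
#' @param a,b [lesion_mask()] objects on the same grid.
#' @return discrepancy fraction (0 = identical volumes).
#' @export
mask_discrepancy <- function(a, b) {
  stopifnot(inherits(a, "lesion_mask"), inherits(b, "lesion_mask"))
  if (!grid_equal(a$grid, b$grid)) stop_grid_mismatch(a$grid, b$grid, "masks")
  va <- sum(a$voxels); vb <- sum(b$voxels)
  if (va + vb == 0L) stop("both masks are empty: discrepancy undefined",
                          call. = FALSE)
  abs(va - vb) / ((va + vb) / 2)
}

#' Merge two raters' masks into a consensus mask
#'
#' Voxelwise union, allowed only when the volume discrepancy is below
#' `max_discrepancy` (default 5%); larger disagreements are refused so they
#' can be routed to an adjudicating rater.
#'
#' @param a,b [lesion_mask()] objects on the same grid.
#' @param max_discrepancy refusal threshold on [mask_discrepancy()].
#' @return merged [lesion_mask()] (patient id taken from `a`).
#' @export
merge_masks <- function(a, b, max_discrepancy = 0.05) {
  d <- mask_discrepancy(a, b)
  if (d >= max_discrepancy)
    stop(sprintf(paste0("mask discrepancy %.4f >= %.4f for patient %s: ",
                        "refusing to merge (adjudication required)"),
                 d, max_discrepancy, a$patient_id), call. = FALSE)
  lesion_mask(a$patient_id, a$grid, a$voxels | b$voxels)
}

#' Read and validate a clinical table
#'
#' Reads a TSV/CSV (by extension) with required columns `patient_id`, `age`,
#' `sex`, `kps`, `time`, `event`, `subgroup`; `tumor_volume_cm3` is
#' optional. Validation enforces unique ids, `sex` in male/female, KPS a
#' multiple of 10 in \[0, 100\], `time` > 0 and `event` in \{0, 1\}.
#'
#' @param path table path (`.tsv` or `.csv`).
#' @return validated data.frame.
#' @export
read_clinical <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' @rdname read_clinical
#' @param df a clinical data.frame to validate in memory.
#' @export
validate_clinical <- function(df) {
  required <- c("patient_id", "age", "sex", "kps", "time", "event", "subgroup")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("clinical table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]),
               collapse = ", "), call. = FALSE)
  for (col in c("age", "kps", "time", "event"))
    if (any(is.na(df[[col]])))
      stop("missing values in `", col, "` for patients: ",
           paste(df$patient_id[is.na(df[[col]])], collapse = ", "),
           call. = FALSE)
  if (!all(df$sex %in% c("male", "female")))
    stop("`sex` must be 'male' or 'female'", call. = FALSE)
  if (!all(df$kps %in% seq(0, 100, 10)))
    stop("`kps` must be multiples of 10 in [0, 100]", call. = FALSE)
  if (any(df$time <= 0)) stop("`time` must be > 0", call. = FALSE)
  if (!all(df$event %in% c(0, 1))) stop("`event` must be 0 or 1", call. = FALSE)
  if (any(df$age <= 0)) stop("`age` must be positive", call. = FALSE)
  df
}

#' Write a clinical table as TSV
#' @param df clinical data.frame.
#' @param path output path.
#' @export
write_clinical <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 8))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stack a cohort of lesion masks into a patients-by-voxels matrix
#'
#' Row order follows the clinical table; every clinical patient must have
#' exactly one mask and all masks must share one grid. The stack holds the
#' voxelwise GLM's dependent data: row i, column v is 1 iff patient i's
#' lesion covers voxel v.
#'
#' @param masks list of [lesion_mask()] objects.
#' @param clinical validated clinical data.frame (see [read_clinical()]).
#' @return object of class `lesion_stack` with fields `data`
#'   (n_patients x n_voxels integer matrix), `patient_ids`, `grid`.
#' @export
build_stack <- function(masks, clinical) {
  clinical <- validate_clinical(clinical)
  ids <- vapply(masks, function(m) m$patient_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate masks for patients: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  missing_ids <- setdiff(clinical$patient_id, ids)
  if (length(missing_ids))
    stop("no mask for patients: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  if (nrow(clinical) < 2L) stop("need at least 2 patients", call. = FALSE)
  grid <- masks[[1]]$grid
  for (m in masks)
    if (!grid_equal(m$grid, grid)) stop_grid_mismatch(m$grid, grid, m$patient_id)
  ord <- match(clinical$patient_id, ids)
  data <- do.call(rbind, lapply(masks[ord],
                                function(m) as.integer(m$voxels)))
  rownames(data) <- clinical$patient_id
  structure(list(data = data, patient_ids = clinical$patient_id, grid = grid),
            class = "lesion_stack")
}

#' @export
print.lesion_stack <- function(x, ...) {
  cat(sprintf("<lesion_stack> %d patients x %d voxels on %s\n",
              nrow(x$data), ncol(x$data), format_grid(x$grid)))
  invisible(x)
}

#' Per-patient geometry report
#'
#' Volume (cm^3) and world-mm centroid for each mask, in mask order.
#'
#' @param masks list of [lesion_mask()] objects.
#' @param path optional TSV output path.
#' @return data.frame with columns patient_id, volume_cm3, centroid_x_mm,
#'   centroid_y_mm, centroid_z_mm.
#' @export
geometry_report <- function(masks, path = NULL) {
  rows <- lapply(masks, function(m) {
    ctr <- mask_centroid(m)
    data.frame(patient_id = m$patient_id, volume_cm3 = mask_volume(m),
               centroid_x_mm = ctr[1], centroid_y_mm = ctr[2],
               centroid_z_mm = ctr[3], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
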