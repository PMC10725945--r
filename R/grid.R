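#' Reference grid for a lesion cohort
#'
#' A reference grid describes the shared voxel lattice on which every mask in
#' a cohort lives: the number of voxels per axis, the voxel size in mm, and
#' the world coordinate (mm) of the *center* of the first voxel. Voxel
#' indices are 0-based in world-coordinate formulas; R arrays remain 1-based.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm numeric vector of length 3, voxel edge lengths in mm
#'   (all > 0).
#' @param origin_mm numeric vector of length 3, world coordinate of the
#'   center of voxel (0,0,0). Defaults to the grid being centered on the
#'   world origin.
#' @param orientation orientation convention identifier (informational).
#' @return an object of class `reference_grid`.
#' @export
reference_grid <- function(shape, voxel_size_mm, origin_mm = NULL,
                           orientation = "RAS") {
  shape <- as.integer(shape)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 positive integers")
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive reals")
  if (is.null(origin_mm)) {
    # center the grid on the world origin
    origin_mm <- -(shape - 1) / 2 * voxel_size_mm
  }
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be 3 finite reals")
  structure(
    list(shape = shape, voxel_size_mm = voxel_size_mm,
         origin_mm = origin_mm, orientation = orientation),
    class = "reference_grid")
}

#' @export
print.reference_grid <- function(x, ...) {
  cat(sprintf("<reference_grid> %d x %d x %d voxels, %.4g x %.4g x %.4g mm, origin (%.4g, %.4g, %.4g) mm [%s]\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3], x$orientation))
  invisible(x)
}

#' Voxel volume of a grid in mm^3
#' @param grid a `reference_grid`.
#' @return scalar voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$voxel_size_mm)

#' Compare two reference grids
#'
#' Shapes must match exactly; voxel sizes and origins are compared within a
#' small absolute tolerance (default 1e-4 mm) to absorb floating-point noise
#' from file headers.
#'
#' @param a,b `reference_grid` objects.
#' @param tol_mm absolute tolerance in mm.
#' @return logical scalar.
#' @export
grid_equal <- function(a, b, tol_mm = 1e-4) {
  stopifnot(inherits(a, "reference_grid"), inherits(b, "reference_grid"))
  identical(a$shape, b$shape) &&
    all(abs(a$voxel_size_mm - b$voxel_size_mm) <= tol_mm) &&
    all(abs(a$origin_mm - b$origin_mm) <= tol_mm)
}

format_grid <- function(g) {
  sprintf("[%s] @ [%s] mm, origin [%s]",
          paste(g$shape, collapse = "x"),
          paste(signif(g$voxel_size_mm, 6), collapse = ", "),
          paste(signif(g$origin_mm, 6), collapse = ", "))
}

stop_grid_mismatch <- function(got, expected, what = "volume") {
  stop(sprintf("grid mismatch for %s:\n  got      %s\n  expected %s",
               what, format_grid(got), format_grid(expected)), call. = FALSE)
}

#' World coordinates of voxel centers
#'
#' Converts 1-based array indices to world mm coordinates of voxel centers:
#' `world = origin + (index - 1) * voxel_size`.
#'
#' @param grid a `reference_grid`.
#' @param idx integer matrix (n x 3) of 1-based array indices.
#' @return numeric matrix (n x 3) of world coordinates in mm.
#' @export
voxel_to_world <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, grid$voxel_size_mm, `*`), 2, grid$origin_mm, `+`)
}

#' World point to containing voxel index
#'
#' Each voxel owns the half-open cube centered on it; a point exactly on a
#' face boundary belongs to the higher-index voxel (floor rule on
#' `(p - origin)/size + 1/2`).
#'
#' @param grid a `reference_grid`.
#' @param point_mm numeric length-3 world coordinate.
#' @return integer length-3 1-based array index.
#' @export
world_to_voxel <- function(grid, point_mm) {
  stopifnot(length(point_mm) == 3L, all(is.finite(point_mm)))
  i0 <- floor((point_mm - grid$origin_mm) / grid$voxel_size_mm + 0.5)
  if (any(i0 < 0) || any(i0 > grid$shape - 1))
    stop(sprintf("point (%s) mm is outside the grid %s",
                 paste(signif(point_mm, 6), collapse = ", "),
                 format_grid(grid)), call. = FALSE)
  as.integer(i0) + 1L
}

# per-axis voxel-center world coordinates, as a list of 3 vectors
axis_coords <- function(grid) {
  lapply(1:3, function(a)
    grid$origin_mm[a] + (seq_len(grid$shape[a]) - 1) * grid$voxel_size_mm[a])
}
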