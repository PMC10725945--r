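# Shared fixtures: tiny grids, hand-built masks, small cohorts.

tiny_grid <- function(shape = c(6L, 6L, 6L), vs = c(2, 2, 2),
                      origin = c(0, 0, 0)) {
  reference_grid(shape, vs, origin)
}

# mask from a set of 1-based voxel indices (n x 3 matrix or vector triplets)
mask_from_indices <- function(grid, idx, patient_id = "P1") {
  v <- array(0L, dim = grid$shape)
  idx <- matrix(idx, ncol = 3, byrow = is.null(dim(idx)))
  for (r in seq_len(nrow(idx))) v[idx[r, 1], idx[r, 2], idx[r, 3]] <- 1L
  lesion_mask(patient_id, grid, v)
}

# cuboid mask spanning inclusive 1-based index ranges
cuboid_mask <- function(grid, xr, yr, zr, patient_id = "P1") {
  v <- array(0L, dim = grid$shape)
  v[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- 1L
  lesion_mask(patient_id, grid, v)
}

small_clinical <- function(n = 4, seed = 1) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = round(runif(n, 30, 75), 1),
    sex = rep(c("male", "female"), length.out = n),
    kps = sample(seq(40, 100, 10), n, replace = TRUE),
    time = round(rexp(n, 0.05) + 0.5, 3),
    event = rbinom(n, 1, 0.7),
    subgroup = "GBM",
    tumor_volume_cm3 = round(runif(n, 5, 80), 2),
    stringsAsFactors = FALSE)
}

# fast in-memory cohort for pipeline-level tests
small_cohort <- function(n = 30, seed = 1, ...) {
  generate_cohort(sim_config(
    grid = reference_grid(c(16L, 16L, 16L), c(8, 8, 8)),
    n_patients = n, seed = seed,
    effect_radii_mm = c(24, 24, 24),
    lesion_radius_range_mm = c(14, 34), ...))
}
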