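# Synthetic lesion-cohort generation.
#
# The generator states a small, explicit world: ellipsoidal "tumor" blobs
# whose centers cluster near the middle of a brain-shaped region, a fixed
# ellipsoidal ground-truth effect region where lesion presence lowers the
# performance score and raises the death hazard, covariates on the scale of
# adult glioma cohorts, and exponential survival with independent
# exponential censoring. Everything downstream (VLSM, atlas overlap,
# survival validation) is exercised against this world and its known truth.

set_seed_strict <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Simulation configuration
#'
#' Defaults describe a GBM-like cohort: ages 58 +/- 15 y, KPS 85 +/- 13
#' before lesion effects, exponential survival with baseline hazard
#' 0.05/month (median ~14 months), 30% censoring, lesions of mean volume
#' ~35 cm^3 whose centers cluster centrally (truncated isotropic normal,
#' sd 30 mm, inside a 70/85/70 mm brain ellipsoid), and a central effect
#' region of radii (20, 24, 20) mm in which lesion presence shifts KPS by
#' `kps_effect` and multiplies the hazard by `exp(os_log_hazard_effect)`.
#'
#' @param grid reference grid (default 40 x 48 x 40 voxels at 4 mm, centered
#'   on the origin: 76,800 voxels, small enough for permutation VLSM on one
#'   CPU).
#' @param n_patients cohort size (>= 10).
#' @param seed integer RNG seed; fixed seed implies identical output.
#' @param effect_center_mm,effect_radii_mm ellipsoidal ground-truth effect
#'   region (world mm).
#' @param lesion_radius_range_mm min/max base lesion radius; per-axis radii
#'   are jittered +/-25% around the base.
#' @param lesion_center_sd_mm sd of the isotropic normal from which lesion
#'   centers are drawn (truncated to the brain ellipsoid).
#' @param brain_radii_mm semi-axes of the brain ellipsoid confining lesion
#'   centers.
#' @param kps_effect mean KPS shift (<= 0) when the lesion touches the
#'   effect region.
#' @param os_log_hazard_effect log hazard ratio (>= 0) for effect-region
#'   overlap.
#' @param baseline_kps_mean,baseline_kps_sd pre-effect KPS distribution.
#' @param baseline_hazard exponential event hazard per time unit (months).
#' @param censor_rate target fraction censored, in \[0, 1).
#' @param age_mean,age_sd age distribution (years), truncated at >= 18.
#' @param male_fraction P(male).
#' @param subgroup label written to the clinical table.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(grid = reference_grid(c(40L, 48L, 40L), c(4, 4, 4)),
                       n_patients = 120L,
                       seed = 1L,
                       effect_center_mm = c(0, 0, 0),
                       effect_radii_mm = c(20, 24, 20),
                       lesion_radius_range_mm = c(10, 30),
                       lesion_center_sd_mm = 30,
                       brain_radii_mm = c(70, 85, 70),
                       kps_effect = -20,
                       os_log_hazard_effect = log(2),
                       baseline_kps_mean = 85,
                       baseline_kps_sd = 13,
                       baseline_hazard = 0.05,
                       censor_rate = 0.3,
                       age_mean = 58,
                       age_sd = 15,
                       male_fraction = 0.55,
                       subgroup = "GBM") {
  stopifnot(inherits(grid, "reference_grid"))
  n_patients <- as.integer(n_patients)
  if (n_patients < 10L) stop("n_patients must be >= 10", call. = FALSE)
  if (kps_effect > 0) stop("kps_effect must be <= 0", call. = FALSE)
  if (os_log_hazard_effect < 0)
    stop("os_log_hazard_effect must be >= 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  if (length(lesion_radius_range_mm) != 2L ||
      lesion_radius_range_mm[1] <= 0 || diff(lesion_radius_range_mm) < 0)
    stop("lesion_radius_range_mm must be (min, max) with 0 < min <= max",
         call. = FALSE)
  lo <- grid$origin_mm - grid$voxel_size_mm / 2
  hi <- grid$origin_mm + (grid$shape - 0.5) * grid$voxel_size_mm
  if (any(effect_center_mm - effect_radii_mm < lo) ||
      any(effect_center_mm + effect_radii_mm > hi))
    stop("effect region does not fit inside the grid", call. = FALSE)
  structure(list(
    grid = grid, n_patients = n_patients, seed = as.integer(seed),
    effect_center_mm = effect_center_mm, effect_radii_mm = effect_radii_mm,
    lesion_radius_range_mm = lesion_radius_range_mm,
    lesion_center_sd_mm = lesion_center_sd_mm,
    brain_radii_mm = brain_radii_mm,
    kps_effect = kps_effect, os_log_hazard_effect = os_log_hazard_effect,
    baseline_kps_mean = baseline_kps_mean, baseline_kps_sd = baseline_kps_sd,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    age_mean = age_mean, age_sd = age_sd, male_fraction = male_fraction,
    subgroup = subgroup), class = "sim_config")
}

# binary ellipsoid voxelization by voxel-center inclusion
ellipsoid_mask <- function(grid, center_mm, radii_mm) {
  ax <- axis_coords(grid)
  a <- ((ax[[1]] - center_mm[1]) / radii_mm[1])^2
  b <- ((ax[[2]] - center_mm[2]) / radii_mm[2])^2
  c3 <- ((ax[[3]] - center_mm[3]) / radii_mm[3])^2
  q <- outer(outer(a, b, `+`), c3, `+`)
  array(as.integer(q <= 1), dim = grid$shape)
}

#' Generate a synthetic lesion cohort with known ground truth
#'
#' Per patient (in patient order): a lesion center is drawn from a
#' truncated isotropic normal inside the brain ellipsoid, a base radius
#' from the configured range, and per-axis radii with +/-25% jitter; the
#' lesion is voxelized by center inclusion. A patient "overlaps" when the
#' lesion shares at least one voxel with the effect region. Then KPS =
#' clip-and-round-to-10(Normal(baseline) + kps_effect * overlap), survival
#' is exponential with hazard `baseline_hazard * exp(os_log_hazard_effect *
#' overlap)`, censoring is an independent exponential calibrated to the
#' configured censoring fraction, age is truncated normal (>= 18) and sex
#' Bernoulli.
#'
#' @param config a [sim_config()].
#' @return list with `clinical` (data.frame), `masks` (list of
#'   [lesion_mask()]), `ground_truth` (list: `effect_mask` 3D array,
#'   `overlap` logical vector, `config`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$grid
  set_seed_strict(config$seed)
  n <- config$n_patients

  effect_mask <- ellipsoid_mask(g, config$effect_center_mm,
                                config$effect_radii_mm)
  eff_idx <- which(effect_mask == 1L)

  masks <- vector("list", n)
  overlap <- logical(n)
  volume_cm3 <- numeric(n)
  ids <- sprintf("P%03d", seq_len(n))
  for (i in seq_len(n)) {
    repeat {  # truncated normal center inside the brain ellipsoid
      ctr <- stats::rnorm(3, 0, config$lesion_center_sd_mm)
      if (sum((ctr / config$brain_radii_mm)^2) <= 1) break
    }
    base_r <- stats::runif(1, config$lesion_radius_range_mm[1],
                           config$lesion_radius_range_mm[2])
    radii <- base_r * stats::runif(3, 0.75, 1.25)
    vox <- ellipsoid_mask(g, ctr, radii)
    masks[[i]] <- lesion_mask(ids[i], g, vox)
    overlap[i] <- any(vox[eff_idx] == 1L)
    volume_cm3[i] <- sum(vox) * voxel_volume_mm3(g) / 1000
  }

  kps_raw <- stats::rnorm(n, config$baseline_kps_mean, config$baseline_kps_sd) +
    config$kps_effect * overlap
  kps <- pmin(100, pmax(0, round(kps_raw / 10) * 10))

  p18 <- stats::pnorm(18, config$age_mean, config$age_sd)
  age <- stats::qnorm(p18 + stats::runif(n) * (1 - p18),
                      config$age_mean, config$age_sd)
  sex <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")

  hazard <- config$baseline_hazard * exp(config$os_log_hazard_effect * overlap)
  t_event <- stats::rexp(n, hazard)
  if (config$censor_rate > 0) {
    # P(C < T) for competing exponentials is rc / (rc + h); calibrate rc
    # against the cohort's mean hazard so the realized censoring fraction
    # tracks censor_rate
    rc <- config$censor_rate / (1 - config$censor_rate) * mean(hazard)
    t_cens <- stats::rexp(n, rc)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }

  clinical <- data.frame(
    patient_id = ids, age = age, sex = sex, kps = as.integer(kps),
    time = time, event = event, subgroup = config$subgroup,
    tumor_volume_cm3 = volume_cm3, stringsAsFactors = FALSE)

  list(clinical = validate_clinical(clinical), masks = masks,
       ground_truth = list(effect_mask = effect_mask, overlap = overlap,
                           config = config))
}

#' Generate a synthetic tract atlas
#'
#' A stand-in for a white-matter tractography atlas: each "tract" is a tube
#' (cylinder) of random axis, radius 6-14 mm and random offset near the
#' brain center. Tracts are named `tract_01`, `tract_02`, ...
#'
#' @param grid a [reference_grid()].
#' @param n_tracts number of tracts (>= 1).
#' @param seed RNG seed.
#' @return named list of `atlas_tract` objects (fields `name`, `mask`,
#'   `voxel_count`, `grid`).
#' @export
generate_atlas <- function(grid, n_tracts, seed = 1L) {
  stopifnot(inherits(grid, "reference_grid"))
  if (n_tracts < 1L) stop("n_tracts must be >= 1", call. = FALSE)
  set_seed_strict(seed)
  ax <- axis_coords(grid)
  extent <- grid$shape * grid$voxel_size_mm
  out <- vector("list", n_tracts)
  names(out) <- sprintf("tract_%02d", seq_len(n_tracts))
  for (k in seq_len(n_tracts)) {
    axis <- sample(1:3, 1)
    perp <- setdiff(1:3, axis)
    ctr <- stats::rnorm(2, 0, 20)
    radius <- stats::runif(1, 6, 14)
    half_len <- stats::runif(1, 0.25, 0.45) * extent[axis]
    mid <- stats::rnorm(1, 0, 15)
    d1 <- ((ax[[perp[1]]] - ctr[1]) / radius)^2
    d2 <- ((ax[[perp[2]]] - ctr[2]) / radius)^2
    along <- abs(ax[[axis]] - mid) <= half_len
    dims <- c(perp[1], perp[2], axis)
    q <- outer(outer(d1, d2, `+`) <= 1, along, `&`)
    vox <- array(0L, dim = grid$shape[dims])
    vox[q] <- 1L
    vox <- aperm(vox, order(dims))
    if (sum(vox) == 0L) {  # degenerate tube off-grid: fall back to a blob
      vox <- ellipsoid_mask(grid, c(0, 0, 0), rep(radius, 3))
    }
    out[[k]] <- structure(list(name = names(out)[k], mask = vox,
                               voxel_count = sum(vox), grid = grid),
                          class = "atlas_tract")
  }
  out
}

#' Write a simulated cohort to disk
#'
#' Lays out the same formats [read_mask()] and [read_clinical()] consume:
#' `masks/<patient_id>.nii.gz`, `clinical.tsv`, plus
#' `ground_truth/effect_region.nii.gz` and a JSON sidecar echoing the
#' configuration.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  mask_dir <- file.path(dir, "masks")
  gt_dir <- file.path(dir, "ground_truth")
  dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(gt_dir, recursive = TRUE, showWarnings = FALSE)
  for (m in cohort$masks)
    write_mask(m, file.path(mask_dir, paste0(m$patient_id, ".nii.gz")))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  cfg <- cohort$ground_truth$config
  write_nifti_volume(cohort$ground_truth$effect_mask, cfg$grid,
                     file.path(gt_dir, "effect_region.nii.gz"), "uint8")
  sidecar <- c(unclass(cfg)[setdiff(names(unclass(cfg)), "grid")],
               list(grid = list(shape = cfg$grid$shape,
                                voxel_size_mm = cfg$grid$voxel_size_mm,
                                origin_mm = cfg$grid$origin_mm),
                    overlap_prevalence = mean(cohort$ground_truth$overlap)))
  jsonlite::write_json(sidecar, file.path(gt_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write an atlas as a directory of binary NIfTI masks
#' @param atlas list of tracts from [generate_atlas()].
#' @param dir output directory.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in atlas)
    write_nifti_volume(tr$mask, tr$grid,
                       file.path(dir, paste0(tr$name, ".nii.gz")), "uint8")
  invisible(dir)
}

#' Read an atlas from a directory of binary NIfTI masks
#'
#' Tract names are the file name stems.
#'
#' @param dir directory of `.nii` / `.nii.gz` binary masks.
#' @param expected_grid cohort [reference_grid()].
#' @return named list of `atlas_tract` objects.
#' @export
read_atlas_dir <- function(dir, expected_grid) {
  files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (!length(files)) stop("no NIfTI masks found in ", dir, call. = FALSE)
  out <- lapply(files, function(f) {
    vol <- read_nifti_volume(f)
    if (!grid_equal(vol$grid, expected_grid))
      stop_grid_mismatch(vol$grid, expected_grid, f)
    m <- array(as.integer(vol$data > 0.5), dim = expected_grid$shape)
    name <- sub("\\.nii(\\.gz)?$", "", basename(f))
    structure(list(name = name, mask = m, voxel_count = sum(m),
                   grid = expected_grid), class = "atlas_tract")
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}
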