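# End-to-end orchestration: simulate -> VLSM -> atlas overlap -> survival
# validation, driven by one YAML/list config with deterministic per-stage
# seeding and a run manifest with output checksums.

PIPELINE_KEYS <- c("masks_dir", "clinical_table", "atlas_dir", "out_dir",
                   "outcomes", "covariates", "alpha", "n_permutations",
                   "min_lesion_count", "threshold_mode", "permute_scheme",
                   "log_time", "horizon_time", "n_boot", "seed", "log_level",
                   "subgroup", "simulation")
SIMULATION_KEYS <- c("n_patients", "grid_shape", "voxel_size_mm",
                     "origin_mm", "effect_center_mm", "effect_radii_mm",
                     "lesion_radius_range_mm", "lesion_center_sd_mm",
                     "brain_radii_mm", "kps_effect", "os_log_hazard_effect",
                     "baseline_kps_mean", "baseline_kps_sd",
                     "baseline_hazard", "censor_rate", "age_mean", "age_sd",
                     "male_fraction", "subgroup", "n_tracts")

#' Deterministic per-stage seed derivation
#'
#' Spawning rule: `seed_stage = (seed * 48271 + h(stage)) mod (2^31 - 1)`,
#' with `h` the position-weighted sum of the stage name's character codes.
#' Documented so any stage can be re-run in isolation with its own seed.
#'
#' @param seed global integer seed.
#' @param stage stage name (character).
#' @return integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- ((as.numeric(seed) %% 2147483647) * 48271 + h) %% 2147483647
  as.integer(max(1, s))
}

#' Load and validate a pipeline configuration
#'
#' Reads YAML (or accepts a list), applies defaults, and rejects unknown
#' keys outright — a typo in an analysis setting must fail loudly, not be
#' silently ignored.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(config$simulation)) {
    bad <- setdiff(names(config$simulation), SIMULATION_KEYS)
    if (length(bad))
      stop("unknown simulation keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  defaults <- list(outcomes = c("kps", "os"),
                   covariates = c("age", "sex", "volume"),
                   alpha = 0.05, n_permutations = 500L,
                   threshold_mode = "pervoxel", permute_scheme = "simple",
                   log_time = FALSE, horizon_time = 12, n_boot = 2000L,
                   seed = 1L, log_level = "info", subgroup = "GBM")
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$out_dir)) stop("config needs `out_dir`", call. = FALSE)
  if (!all(config$outcomes %in% c("kps", "os")))
    stop("outcomes must be among kps, os", call. = FALSE)
  for (p in c("masks_dir", "clinical_table", "atlas_dir"))
    if (!is.null(config[[p]]) && !file.exists(config[[p]]))
      stop("config path `", p, "` does not exist: ", config[[p]],
           call. = FALSE)
  structure(config, class = c("pipeline_config", "list"))
}

pipe_log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[lesionmap %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(...)))
}

canonical_roi_label <- function(outcome, subgroup) {
  if (identical(subgroup, "GBM") && outcome == "kps") return("ROI1")
  if (identical(subgroup, "GBM") && outcome == "os") return("ROI2")
  if (identical(subgroup, "astrocytoma") && outcome == "kps") return("ROI3")
  paste0("ROI_", outcome, "_", subgroup)
}

write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(path, ".tmp")
  manifest$files <- manifest_checksums(out_dir, exclude = basename(path))
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)  # atomic: no partial manifest after a crash
  manifest
}

manifest_checksums <- function(out_dir, exclude = character(0)) {
  files <- sort(list.files(out_dir, recursive = TRUE))
  files <- setdiff(files, exclude)
  sums <- unname(tools::md5sum(file.path(out_dir, files)))
  as.list(stats::setNames(sums, files))
}

read_cohort_dir <- function(masks_dir, clinical_table) {
  clinical <- read_clinical(clinical_table)
  files <- list.files(masks_dir, pattern = "\\.nii(\\.gz)?$",
                      full.names = TRUE)
  if (!length(files)) stop("no masks in ", masks_dir, call. = FALSE)
  first <- read_nifti_volume(files[[1]])
  grid <- first$grid
  masks <- lapply(files, read_mask, expected_grid = grid)
  list(clinical = clinical, masks = masks, grid = grid)
}

#' Run the discovery arm: VLSM per outcome, ROI extraction, atlas overlap
#'
#' Reads the cohort (masks directory + clinical table), runs the voxelwise
#' GLM with permutation/FDR inference once per requested outcome, writes
#' the t-map, permutation p-map and ROI as NIfTI plus the atlas overlap
#' TSVs, and ends with an atomically written manifest.
#'
#' @param config a [pipeline_config()] (or path/list coercible to one).
#' @return the manifest, invisibly; ROIs are attached as attribute
#'   `"rois"`.
#' @export
run_discovery <- function(config) {
  config <- pipeline_config(config)
  t_start <- Sys.time()
  out_dir <- file.path(config$out_dir, "discovery")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- read_cohort_dir(config$masks_dir, config$clinical_table)
  if (nrow(cohort$clinical) < 10L)
    stop("cohort has ", nrow(cohort$clinical),
         " patients; at least 10 required", call. = FALSE)
  clinical <- cohort$clinical
  if (is.null(clinical$tumor_volume_cm3))
    clinical$tumor_volume_cm3 <-
      vapply(cohort$masks, mask_volume, numeric(1))[
        match(clinical$patient_id,
              vapply(cohort$masks, `[[`, character(1), "patient_id"))]
  stack <- build_stack(cohort$masks, clinical)
  pipe_log(config, "discovery: %d patients, %d voxels",
           nrow(stack$data), ncol(stack$data))

  atlas <- if (!is.null(config$atlas_dir))
    read_atlas_dir(config$atlas_dir, stack$grid) else NULL

  stages <- list()
  rois <- list()
  for (outcome in config$outcomes) {
    seed <- derive_seed(config$seed, paste0("vlsm_", outcome))
    spec <- design_spec(outcome = outcome, covariates = config$covariates,
                        min_lesion_count = config$min_lesion_count,
                        alpha = config$alpha,
                        n_permutations = config$n_permutations,
                        seed = seed, threshold_mode = config$threshold_mode,
                        permute_scheme = config$permute_scheme,
                        log_time = config$log_time)
    label <- canonical_roi_label(outcome, config$subgroup)
    t0 <- Sys.time()
    res <- run_vlsm(stack, clinical, spec, label = label,
                    subgroup = config$subgroup)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    rois[[label]] <- res$roi

    if (!is.null(res$statmap)) {
      write_nifti_volume(res$statmap$t_adv, stack$grid,
                         file.path(out_dir, paste0("tmap_", outcome, ".nii.gz")),
                         "float32")
      pmap <- array(NaN, dim = stack$grid$shape)
      pmap[res$null$analyzed_idx] <- res$null$p
      write_nifti_volume(pmap, stack$grid,
                         file.path(out_dir, paste0("pmap_", outcome, ".nii.gz")),
                         "float32")
    }
    write_nifti_volume(res$roi$voxels, stack$grid,
                       file.path(out_dir, paste0(label, ".nii.gz")), "uint8")
    if (!is.null(atlas))
      write_overlap_table(overlap_table(res$roi, atlas),
                          file.path(out_dir, paste0("overlap_", label, ".tsv")))
    n_sig <- sum(res$roi$voxels)
    pipe_log(config, "vlsm[%s]: %d analyzed voxels, %d significant (%s)",
             outcome, sum(res$analyzed), n_sig, label)
    stages[[paste0("vlsm_", outcome)]] <-
      list(seed = seed, label = label,
           min_lesion_count = res$min_lesion_count,
           n_analyzed = sum(res$analyzed), n_significant = n_sig,
           wall_clock_s = round(elapsed, 3))
  }
  geometry_report(cohort$masks, file.path(out_dir, "geometry.tsv"))

  manifest <- list(
    kind = "discovery", version = pkg_version(), seed = config$seed,
    config = unclass(config), n_patients = nrow(clinical),
    stages = stages, status = "complete",
    wall_clock_s = round(as.numeric(difftime(Sys.time(), t_start,
                                             units = "secs")), 3))
  manifest <- write_manifest(manifest, out_dir)
  attr(manifest, "rois") <- rois
  invisible(manifest)
}

pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("lesionmap")),
           error = function(e) "dev")
}

#' Run the validation arm: risk groups, KM/log-rank, Cox, horizon ROC
#'
#' Assigns high/low risk by ROI involvement, then (when both groups are
#' populated) Kaplan-Meier curves per group, the log-rank test, the
#' univariate Cox hazard ratio, and the fixed-horizon ROC using the total
#' ROI-overlap voxel count as the marker (plus the binary indicator
#' variant). Degenerate single-group assignments skip the statistics with
#' a warning but still write the assignment.
#'
#' @param config a [pipeline_config()].
#' @param rois list of `roi_mask` objects (e.g. from [run_discovery()]).
#' @return manifest, invisibly; the stats list is attached as attribute
#'   `"stats"`.
#' @export
run_validation <- function(config, rois) {
  config <- pipeline_config(config)
  t_start <- Sys.time()
  out_dir <- file.path(config$out_dir, "validation")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- read_cohort_dir(config$masks_dir, config$clinical_table)
  clinical <- cohort$clinical
  for (r in rois)
    if (!grid_equal(r$grid, cohort$grid))
      stop_grid_mismatch(r$grid, cohort$grid, r$label)

  assignment <- assign_risk_groups(cohort$masks, rois)
  assignment <- assignment[match(clinical$patient_id, assignment$patient_id), ]
  utils::write.table(assignment, file.path(out_dir, "risk_assignment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  groups <- assignment$risk_group
  stats_out <- list(horizon = config$horizon_time,
                    n_high = sum(groups == "high"),
                    n_low = sum(groups == "low"))
  if (length(unique(groups)) < 2L) {
    warning("all patients fall in one risk group ('", unique(groups),
            "'): survival statistics skipped", call. = FALSE)
    stats_out$skipped <- "single risk group"
  } else {
    hi <- groups == "high"
    km_high <- km_estimate(clinical$time[hi], clinical$event[hi])
    km_low <- km_estimate(clinical$time[!hi], clinical$event[!hi])
    km_tab <- rbind(cbind(group = "high", km_high$curve),
                    cbind(group = "low", km_low$curve))
    utils::write.table(km_tab, file.path(out_dir, "km_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    lr <- logrank_test(clinical$time[hi], clinical$event[hi],
                       clinical$time[!hi], clinical$event[!hi])
    cox <- cox_hazard_ratio(clinical$time, clinical$event, groups,
                            reference = "high")
    roc_seed <- derive_seed(config$seed, "roc_bootstrap")
    roc <- tryCatch(
      roc_at_horizon(assignment$total_overlap_voxels, clinical$time,
                     clinical$event, config$horizon_time,
                     n_boot = config$n_boot, seed = roc_seed),
      error = function(e) e)
    roc_bin <- tryCatch(
      roc_at_horizon(as.numeric(groups == "high"), clinical$time,
                     clinical$event, config$horizon_time,
                     n_boot = config$n_boot, seed = roc_seed),
      error = function(e) e)
    stats_out$logrank_chisq <- lr$chisq
    stats_out$logrank_p <- lr$p
    stats_out$hr_low_vs_high <- cox$hr
    stats_out$hr_ci <- cox$ci
    stats_out$hr_p <- cox$p
    if (!inherits(roc, "error")) {
      stats_out$auc <- roc$auc
      stats_out$auc_ci <- roc$ci
      stats_out$n_excluded_censored <- roc$n_excluded_censored
    } else stats_out$auc_error <- conditionMessage(roc)
    if (!inherits(roc_bin, "error")) stats_out$auc_binary <- roc_bin$auc
    pipe_log(config, "validation: logrank p = %.4g, HR(low vs high) = %.3f",
             lr$p, cox$hr)
  }
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    kind = "validation", version = pkg_version(), seed = config$seed,
    config = unclass(config), n_patients = nrow(clinical),
    rois = vapply(rois, function(r) r$label, character(1)),
    status = "complete",
    wall_clock_s = round(as.numeric(difftime(Sys.time(), t_start,
                                             units = "secs")), 3))
  manifest <- write_manifest(manifest, out_dir)
  attr(manifest, "stats") <- stats_out
  invisible(manifest)
}

#' Simulate, discover and validate in one deterministic run
#'
#' With a `simulation` block in the config, simulates a discovery cohort, a
#' validation cohort sharing the same effect region (different derived
#' seed) and a synthetic tract atlas, writes them under `out_dir`, then
#' runs [run_discovery()] and [run_validation()]. One global seed
#' deterministically spawns every stage seed (see [derive_seed()]).
#'
#' @param config a [pipeline_config()] with a `simulation` block.
#' @return list with both manifests and the validation stats.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  if (is.null(config$simulation))
    stop("run_pipeline needs a `simulation` block; use run_discovery/",
         "run_validation directly for on-disk cohorts", call. = FALSE)
  sim <- config$simulation
  grid <- reference_grid(
    if (!is.null(sim$grid_shape)) sim$grid_shape else c(40L, 48L, 40L),
    if (!is.null(sim$voxel_size_mm)) sim$voxel_size_mm else c(4, 4, 4),
    sim$origin_mm)
  base_args <- sim[setdiff(names(sim), c("grid_shape", "voxel_size_mm",
                                         "origin_mm", "n_tracts"))]
  make_cfg <- function(seed)
    do.call(sim_config, c(list(grid = grid, seed = seed), base_args))

  out_dir <- config$out_dir
  disc_dir <- file.path(out_dir, "cohort_discovery")
  val_dir <- file.path(out_dir, "cohort_validation")
  pipe_log(config, "simulating discovery + validation cohorts")
  disc <- generate_cohort(make_cfg(derive_seed(config$seed, "simulate_discovery")))
  val <- generate_cohort(make_cfg(derive_seed(config$seed, "simulate_validation")))
  write_cohort(disc, disc_dir)
  write_cohort(val, val_dir)
  n_tracts <- if (!is.null(sim$n_tracts)) sim$n_tracts else 6L
  atlas_dir <- file.path(out_dir, "atlas")
  write_atlas(generate_atlas(grid, n_tracts,
                             seed = derive_seed(config$seed, "atlas")),
              atlas_dir)

  disc_config <- config
  disc_config$masks_dir <- file.path(disc_dir, "masks")
  disc_config$clinical_table <- file.path(disc_dir, "clinical.tsv")
  disc_config$atlas_dir <- atlas_dir
  if (!is.null(sim$subgroup)) disc_config$subgroup <- sim$subgroup
  manifest_disc <- run_discovery(disc_config)

  val_config <- disc_config
  val_config$masks_dir <- file.path(val_dir, "masks")
  val_config$clinical_table <- file.path(val_dir, "clinical.tsv")
  manifest_val <- run_validation(val_config, attr(manifest_disc, "rois"))

  list(discovery = manifest_disc, validation = manifest_val,
       stats = attr(manifest_val, "stats"))
}
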