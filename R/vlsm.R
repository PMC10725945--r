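# Mass-univariate voxelwise GLM with permutation + FDR inference.
#
# Orientation note: the model regresses voxel lesion status (binary, one
# regression per voxel) on the clinical design — a linear-probability
# model with the outcome as the regressor of interest and age/sex/volume as
# nuisance covariates. The map statistic is the t of the outcome
# coefficient, sign-flipped so that "lesion here co-occurs with a LOWER
# outcome" (lower KPS, shorter survival) is positive: t_adv = -t_outcome.
# Significance is a one-sided permutation test in the adverse direction
# combined with Benjamini-Hochberg FDR over the permutation p-values.

#' Analysis design specification for voxelwise lesion-symptom mapping
#'
#' @param outcome `"kps"` or `"os"` (overall survival time; used raw by
#'   default, log-transformed with `log_time = TRUE`).
#' @param covariates subset of `c("age", "sex", "volume")`, in order.
#' @param min_lesion_count voxel inclusion threshold: a voxel is analyzed
#'   only when lesioned in at least this many and spared in at least this
#'   many patients. Default `max(5, ceiling(0.05 * n))`, resolved when the
#'   stack is seen.
#' @param alpha FDR level for ROI extraction.
#' @param n_permutations permutation count (>= 100).
#' @param seed RNG seed for the permutation stream.
#' @param threshold_mode `"pervoxel"` (each voxel compared with the 95th
#'   percentile of its own permutation distribution) or `"maxstat"`
#'   (brain-wise max-statistic threshold).
#' @param permute_scheme `"simple"` (permute the outcome entries across
#'   patients, covariates fixed) or `"freedman_lane"` (permute residuals of
#'   outcome on covariates).
#' @param log_time log-transform survival times before standardization.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(outcome = c("kps", "os"),
                        covariates = c("age", "sex", "volume"),
                        min_lesion_count = NULL,
                        alpha = 0.05,
                        n_permutations = 500L,
                        seed = 1L,
                        threshold_mode = c("pervoxel", "maxstat"),
                        permute_scheme = c("simple", "freedman_lane"),
                        log_time = FALSE) {
  outcome <- match.arg(outcome)
  threshold_mode <- match.arg(threshold_mode)
  permute_scheme <- match.arg(permute_scheme)
  if (!all(covariates %in% c("age", "sex", "volume")))
    stop("covariates must be a subset of age, sex, volume", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 100L)
    stop("n_permutations must be >= 100 (p-value resolution too coarse ",
         "below that for alpha = 0.05 with FDR)", call. = FALSE)
  if (!is.null(min_lesion_count) && min_lesion_count < 1)
    stop("min_lesion_count must be >= 1", call. = FALSE)
  structure(list(outcome = outcome, covariates = covariates,
                 min_lesion_count = min_lesion_count, alpha = alpha,
                 n_permutations = n_permutations, seed = as.integer(seed),
                 threshold_mode = threshold_mode,
                 permute_scheme = permute_scheme, log_time = log_time),
            class = "design_spec")
}

default_min_lesion_count <- function(spec, n) {
  if (!is.null(spec$min_lesion_count)) return(as.integer(spec$min_lesion_count))
  as.integer(max(5, ceiling(0.05 * n)))
}

#' Build the clinical design matrix
#'
#' Columns: intercept, the standardized outcome (KPS or survival time), then
#' standardized continuous covariates; sex is coded male = 1, female = 0 and
#' left unstandardized. Standardization cannot change the t statistics
#' (they are invariant to affine rescaling of regressors) but improves
#' conditioning. Full column rank is verified.
#'
#' @param clinical validated clinical data.frame ([read_clinical()]).
#' @param spec a [design_spec()].
#' @return object of class `design_matrix`: fields `X` (n x p numeric
#'   matrix), `outcome_col` (index of the outcome column), `columns`.
#' @export
build_design <- function(clinical, spec) {
  clinical <- validate_clinical(clinical)
  n <- nrow(clinical)
  outcome_raw <- switch(spec$outcome,
                        kps = clinical$kps,
                        os = if (spec$log_time) log(clinical$time) else clinical$time)
  zstd <- function(x, what) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("rank deficiency: `", what, "` is constant", call. = FALSE)
    (x - mean(x)) / s
  }
  cols <- list(intercept = rep(1, n),
               outcome = zstd(outcome_raw, spec$outcome))
  for (cv in spec$covariates) {
    cols[[cv]] <- switch(cv,
      age = zstd(clinical$age, "age"),
      sex = as.numeric(clinical$sex == "male"),
      volume = {
        if (is.null(clinical$tumor_volume_cm3))
          stop("covariate `volume` requested but tumor_volume_cm3 missing ",
               "from the clinical table", call. = FALSE)
        zstd(clinical$tumor_volume_cm3, "volume")
      })
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (collinear or constant columns)",
         call. = FALSE)
  structure(list(X = X, outcome_col = 2L, columns = colnames(X),
                 patient_ids = clinical$patient_id),
            class = "design_matrix")
}

#' Voxel inclusion mask
#'
#' A voxel enters the analysis only when the lesion count across patients is
#' between `min_lesion_count` and `n - min_lesion_count` (both extremes are
#' near-constant columns that give degenerate fits).
#'
#' @param stack a [build_stack()] result.
#' @param min_lesion_count inclusion threshold (>= 1).
#' @return 3D 0/1 array on the stack grid.
#' @export
voxel_inclusion <- function(stack, min_lesion_count) {
  stopifnot(inherits(stack, "lesion_stack"), min_lesion_count >= 1)
  n <- nrow(stack$data)
  cnt <- colSums(stack$data)
  ok <- cnt >= min_lesion_count & cnt <= n - min_lesion_count
  if (!any(ok))
    warning("no voxel passes the inclusion filter; downstream stages are ",
            "no-ops", call. = FALSE)
  array(as.integer(ok), dim = stack$grid$shape)
}

# Vectorized OLS over all analyzed voxels at once. Y is n x V, X is n x p;
# one normal-equation solve serves every voxel. Returns the adverse-signed
# t vector (t_adv = -t_outcome), betas and df.
ols_adverse_t <- function(X, Y, outcome_col, sum_y2 = NULL) {
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X)
  XtXinv <- solve(XtX)
  XtY <- crossprod(X, Y)
  B <- XtXinv %*% XtY
  if (is.null(sum_y2)) sum_y2 <- colSums(Y * Y)
  rss <- pmax(sum_y2 - colSums(B * XtY), 0)
  df <- n - p
  sigma2 <- rss / df
  se <- sqrt(sigma2 * XtXinv[outcome_col, outcome_col])
  t_out <- unname(B[outcome_col, ] / se)
  t_out[se == 0] <- NaN
  list(t_adv = -t_out, beta = unname(B[outcome_col, ]), df = df)
}

#' Fit the voxelwise GLM
#'
#' For every analyzed voxel v, regresses the binary lesion indicator
#' `Y_v` on the clinical design by OLS and reports the adverse-direction
#' statistic `t_adv(v) = -t_outcome(v)` (positive where lesion presence
#' co-occurs with a lower outcome), with `df = n - p`.
#'
#' @param stack a [build_stack()] result; rows must align with the design.
#' @param design a [build_design()] result.
#' @param analyzed 3D inclusion mask from [voxel_inclusion()].
#' @return object of class `stat_map`: fields `t_adv` and `beta` (3D arrays,
#'   `NaN` outside analyzed voxels), `analyzed`, `df`, `grid`, and
#'   `analyzed_idx`/`t_vec` (linearized forms used by the permutation
#'   machinery).
#' @export
fit_voxelwise_glm <- function(stack, design, analyzed) {
  stopifnot(inherits(stack, "lesion_stack"), inherits(design, "design_matrix"))
  if (!identical(stack$patient_ids, design$patient_ids))
    stop("stack and design rows are not aligned (patient order differs)",
         call. = FALSE)
  idx <- which(analyzed == 1L)
  if (!length(idx)) stop("no analyzed voxels", call. = FALSE)
  Y <- stack$data[, idx, drop = FALSE] * 1.0
  fit <- ols_adverse_t(design$X, Y, design$outcome_col)
  shape <- stack$grid$shape
  t_map <- array(NaN, dim = shape); t_map[idx] <- fit$t_adv
  b_map <- array(NaN, dim = shape); b_map[idx] <- fit$beta
  structure(list(t_adv = t_map, beta = b_map,
                 analyzed = array(as.integer(analyzed == 1L), dim = shape),
                 df = fit$df, grid = stack$grid,
                 analyzed_idx = idx, t_vec = fit$t_adv),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %d analyzed voxels, df = %d, t_adv range [%.3f, %.3f]\n",
              length(x$analyzed_idx), x$df,
              min(x$t_vec, na.rm = TRUE), max(x$t_vec, na.rm = TRUE)))
  invisible(x)
}

#' Permutation null distribution of the voxelwise statistic
#'
#' Repeatedly permutes the outcome column entries across patients (nuisance
#' covariates and lesion data fixed), refits every analyzed voxel, and
#' records the adverse-direction t. Per voxel it returns the 95th-percentile
#' one-sided threshold and the add-one permutation p-value
#' `p(v) = (1 + #{r : t_r(v) >= t_obs(v)}) / (n_permutations + 1)`.
#' With `threshold_mode = "maxstat"` the brain-wise maximum statistic per
#' permutation is used for both threshold and p-values (strong FWE-style
#' control).
#'
#' @param stack,design,analyzed as in [fit_voxelwise_glm()].
#' @param spec a [design_spec()]; `spec$seed` drives the permutation stream.
#' @param statmap optional precomputed [fit_voxelwise_glm()] result (must
#'   match `analyzed`); avoids refitting the observed data.
#' @return object of class `perm_null`: per-voxel `threshold` and `p`
#'   vectors over `analyzed_idx`, plus bookkeeping.
#' @export
permutation_null <- function(stack, design, analyzed, spec, statmap = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  if (is.null(statmap)) statmap <- fit_voxelwise_glm(stack, design, analyzed)
  idx <- statmap$analyzed_idx
  obs <- statmap$t_vec
  n_perm <- spec$n_permutations
  X <- design$X
  n <- nrow(X)
  j <- design$outcome_col
  Y <- stack$data[, idx, drop = FALSE] * 1.0
  sum_y2 <- colSums(Y * Y)

  x_out <- X[, j]
  if (spec$permute_scheme == "freedman_lane") {
    # permute residuals of the outcome on the nuisance block, add back fit
    Z <- X[, -j, drop = FALSE]
    fitted_nuis <- Z %*% solve(crossprod(Z), crossprod(Z, x_out))
    resid_nuis <- x_out - fitted_nuis
  }

  set_seed_strict(spec$seed)
  V <- length(idx)
  perm_t <- matrix(NA_real_, nrow = n_perm, ncol = V)
  Xp <- X
  for (r in seq_len(n_perm)) {
    pidx <- sample.int(n)
    Xp[, j] <- if (spec$permute_scheme == "simple") x_out[pidx]
               else fitted_nuis + resid_nuis[pidx]
    perm_t[r, ] <- ols_adverse_t(Xp, Y, j, sum_y2 = sum_y2)$t_adv
  }

  k95 <- as.integer(ceiling(0.95 * n_perm))
  if (spec$threshold_mode == "maxstat") {
    maxes <- apply(perm_t, 1, max)
    thr <- rep(sort(maxes)[k95], V)
    counts <- vapply(obs, function(t0) sum(maxes >= t0), numeric(1))
  } else {
    thr <- apply(perm_t, 2, function(v) sort(v, partial = k95)[k95])
    counts <- colSums(perm_t >= rep(obs, each = n_perm))
  }
  p <- (1 + counts) / (n_perm + 1)
  structure(list(threshold = thr, p = p, analyzed_idx = idx,
                 n_permutations = n_perm, seed = spec$seed,
                 threshold_mode = spec$threshold_mode,
                 permute_scheme = spec$permute_scheme, grid = statmap$grid),
            class = "perm_null")
}

#' Benjamini-Hochberg step-up FDR
#'
#' Sorts p ascending, finds the largest k with `p_(k) <= k * alpha / m`,
#' rejects the k smallest, and returns monotone adjusted p-values.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param alpha FDR level.
#' @return list with logical `reject` and numeric `p_adjusted`, both in the
#'   input order.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  m <- length(pvalues)
  if (m == 0L) return(list(reject = logical(0), p_adjusted = numeric(0)))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  ord <- order(pvalues)
  ps <- pvalues[ord]
  crit <- seq_len(m) * alpha / m
  k <- suppressWarnings(max(which(ps <= crit)))
  reject_sorted <- rep(FALSE, m)
  if (is.finite(k) && k >= 1) reject_sorted[seq_len(k)] <- TRUE
  adj_sorted <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  reject <- p_adj <- rep(NA, m)
  reject[ord] <- reject_sorted
  p_adj[ord] <- adj_sorted
  list(reject = as.logical(reject), p_adjusted = as.numeric(p_adj))
}

#' Extract a significant region of interest
#'
#' A voxel joins the ROI when (a) its observed adverse t exceeds its
#' permutation 95th-percentile threshold AND (b) BH-FDR over the
#' permutation p-values rejects it at `spec$alpha`. Empty ROIs are valid
#' (some subgroup/outcome pairs genuinely yield none).
#'
#' @param statmap [fit_voxelwise_glm()] result.
#' @param null matching [permutation_null()] result.
#' @param spec the [design_spec()] used for both.
#' @param label ROI label (`"ROI1"`, `"ROI2"`, `"ROI3"`, or custom).
#' @param subgroup optional subgroup tag recorded in the provenance.
#' @param use_threshold set `FALSE` to drop condition (a) (diagnostics
#'   only).
#' @return object of class `roi_mask`: binary 3D `voxels`, `grid`,
#'   `label`, `provenance` list.
#' @export
extract_roi <- function(statmap, null, spec, label = "custom",
                        subgroup = NA_character_, use_threshold = TRUE) {
  stopifnot(inherits(statmap, "stat_map"), inherits(null, "perm_null"))
  if (!identical(statmap$analyzed_idx, null$analyzed_idx))
    stop("stat map and permutation null cover different voxel sets",
         call. = FALSE)
  fdr <- bh_fdr(null$p, spec$alpha)
  sig <- fdr$reject
  if (use_threshold) sig <- sig & (statmap$t_vec > null$threshold)
  vox <- array(0L, dim = statmap$grid$shape)
  vox[statmap$analyzed_idx[sig]] <- 1L
  structure(list(
    voxels = vox, grid = statmap$grid, label = label,
    provenance = list(label = label, subgroup = subgroup,
                      outcome = spec$outcome, alpha = spec$alpha,
                      n_permutations = spec$n_permutations, seed = spec$seed,
                      threshold_rule = if (use_threshold)
                        paste0(null$threshold_mode, "+fdr") else "fdr_only",
                      n_analyzed = length(statmap$analyzed_idx),
                      n_significant = sum(sig))),
    class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s: %d voxels (outcome %s, alpha %.3g, %s)\n",
              x$label, sum(x$voxels), x$provenance$outcome,
              x$provenance$alpha, x$provenance$threshold_rule))
  invisible(x)
}

#' Run the full VLSM stage on one cohort
#'
#' Convenience wrapper: builds the design, applies the inclusion filter,
#' fits the observed map, runs the permutation null and extracts the ROI.
#'
#' @param stack [build_stack()] result.
#' @param clinical validated clinical table.
#' @param spec a [design_spec()].
#' @param label ROI label.
#' @param subgroup subgroup tag recorded in provenance.
#' @return list: `statmap`, `null`, `roi`, `analyzed`, `design`,
#'   `min_lesion_count`.
#' @export
run_vlsm <- function(stack, clinical, spec, label = "custom",
                     subgroup = NA_character_) {
  design <- build_design(clinical, spec)
  mlc <- default_min_lesion_count(spec, nrow(stack$data))
  analyzed <- voxel_inclusion(stack, mlc)
  if (!any(analyzed == 1L)) {
    warning("empty analyzed set: returning an empty ROI", call. = FALSE)
    empty <- array(0L, dim = stack$grid$shape)
    roi <- structure(list(voxels = empty, grid = stack$grid, label = label,
                          provenance = list(label = label, subgroup = subgroup,
                                            outcome = spec$outcome,
                                            alpha = spec$alpha,
                                            n_permutations = spec$n_permutations,
                                            seed = spec$seed,
                                            threshold_rule = "none",
                                            n_analyzed = 0L,
                                            n_significant = 0L)),
                     class = "roi_mask")
    return(list(statmap = NULL, null = NULL, roi = roi, analyzed = analyzed,
                design = design, min_lesion_count = mlc))
  }
  statmap <- fit_voxelwise_glm(stack, design, analyzed)
  null <- permutation_null(stack, design, analyzed, spec, statmap = statmap)
  roi <- extract_roi(statmap, null, spec, label = label, subgroup = subgroup)
  list(statmap = statmap, null = null, roi = roi, analyzed = analyzed,
       design = design, min_lesion_count = mlc)
}

#' Dice coefficient between two binary volumes
#' @param a,b binary 3D arrays (or objects with `$voxels`).
#' @return `2|A∩B| / (|A| + |B|)`; defined as 0 when both are empty.
#' @export
dice_coefficient <- function(a, b) {
  va <- if (is.list(a)) a$voxels else a
  vb <- if (is.list(b)) b$voxels else b
  sa <- sum(va != 0); sb <- sum(vb != 0)
  if (sa + sb == 0) return(0)
  2 * sum(va != 0 & vb != 0) / (sa + sb)
}
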