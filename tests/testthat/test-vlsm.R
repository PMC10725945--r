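# Voxelwise GLM, permutation inference, FDR, ROI extraction.

# independent single-voxel OLS oracle: solve the normal equations directly
# and form the t of the outcome coefficient by the textbook formulas
oracle_t_adv <- function(y, X, j) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * solve(XtX)[j, j])
  -(beta[j] / se)
}

make_vlsm_fixture <- function(n = 120, seed = 3, ...) {
  coh <- generate_cohort(sim_config(n_patients = n, seed = seed, ...))
  stack <- build_stack(coh$masks, coh$clinical)
  list(coh = coh, stack = stack)
}

test_that("build_design: shape, standardization, coding, rank errors", {
  cl <- small_clinical(8)
  spec <- design_spec("kps")
  d <- build_design(cl, spec)
  expect_equal(dim(d$X), c(8L, 5L))
  expect_equal(colnames(d$X), c("intercept", "outcome", "age", "sex", "volume"))
  expect_equal(mean(d$X[, "outcome"]), 0, tolerance = 1e-12)
  expect_equal(sd(d$X[, "age"]), 1, tolerance = 1e-12)
  expect_setequal(unique(d$X[, "sex"]), c(0, 1))
  expect_equal(d$X[, "sex"], as.numeric(cl$sex == "male"))

  const_age <- cl; const_age$age <- 50
  expect_error(build_design(const_age, spec), "constant")
  const_kps <- cl; const_kps$kps <- 80
  expect_error(build_design(const_kps, spec), "constant")
  # OS outcome uses time; log transform requested explicitly
  d_os <- build_design(cl, design_spec("os", log_time = TRUE))
  expect_equal(d_os$X[, "outcome"],
               (log(cl$time) - mean(log(cl$time))) / sd(log(cl$time)))
})

test_that("voxel_inclusion excludes voxels without contrast", {
  g <- tiny_grid(c(2L, 2L, 1L), c(10, 10, 10))
  cl <- small_clinical(10)
  masks <- lapply(seq_len(10), function(i) {
    v <- array(0L, g$shape)
    v[1, 1, 1] <- 1L                        # all patients
    if (i <= 4) v[2, 1, 1] <- 1L            # 4 patients
    if (i == 1) v[1, 2, 1] <- 1L            # 1 patient
    lesion_mask(cl$patient_id[i], g, v)
  })
  st <- build_stack(masks, cl)
  inc <- voxel_inclusion(st, 2)
  expect_equal(inc[1, 1, 1], 0L)  # lesioned in all: no contrast
  expect_equal(inc[2, 1, 1], 1L)  # 4 of 10
  expect_equal(inc[1, 2, 1], 0L)  # below threshold
  expect_equal(inc[2, 2, 1], 0L)  # lesioned in none
  # n = 100-style bound check: count exactly at n/2 always passes
  expect_warning(voxel_inclusion(st, 6), "no voxel")
})

test_that("voxelwise t agrees with the brute-force OLS oracle to 1e-8", {
  fx <- make_vlsm_fixture(n = 60, seed = 5,
                          grid = reference_grid(c(20L, 24L, 20L), c(8, 8, 8)))
  spec <- design_spec("kps", seed = 1)
  design <- build_design(fx$coh$clinical, spec)
  analyzed <- voxel_inclusion(fx$stack, 5)
  sm <- fit_voxelwise_glm(fx$stack, design, analyzed)
  set.seed(99)
  pick <- sample(seq_along(sm$analyzed_idx), 10)
  for (k in pick) {
    y <- fx$stack$data[, sm$analyzed_idx[k]] * 1.0
    expect_equal(sm$t_vec[k], oracle_t_adv(y, design$X, design$outcome_col),
                 tolerance = 1e-8)
  }
  expect_equal(sm$df, 60 - 5)
})

test_that("t_adv sign convention: lesions in the low-outcome patients give positive t", {
  # 20 patients; a synthetic voxel lesioned exactly in the 10 lowest-KPS
  # patients must show a large positive adverse t
  cl <- small_clinical(20, seed = 4)
  cl$kps <- rep(seq(10, 100, 10), 2)
  y <- as.numeric(cl$kps <= 50)
  X <- cbind(intercept = 1, outcome = scale(cl$kps)[, 1])
  t_adv <- oracle_t_adv(y, X, 2)
  expect_gt(t_adv, 5)
  # and the vectorized path agrees
  fit <- lesionmap:::ols_adverse_t(X, matrix(y, ncol = 1), 2)
  expect_equal(fit$t_adv, t_adv, tolerance = 1e-10)
})

test_that("null t_adv distribution matches Student t(df) (KS oracle)", {
  # 1000 voxels of random balanced Y independent of the design: the
  # adverse t must follow Student t(df) (distributional oracle)
  cl <- small_clinical(80, seed = 17)
  design <- build_design(cl, design_spec("kps"))
  set.seed(31)
  Y <- matrix(rbinom(80 * 1000, 1, 0.5), 80, 1000)
  fit <- lesionmap:::ols_adverse_t(design$X, Y, design$outcome_col)
  ks <- suppressWarnings(stats::ks.test(fit$t_adv, stats::pt, df = fit$df))
  expect_gt(ks$p.value, 0.01)
})

test_that("bh_fdr reproduces the hand-applied step-up rule", {
  r <- bh_fdr(c(0.01, 0.5), 0.05)
  expect_equal(r$reject, c(TRUE, FALSE))      # 0.01 <= 0.025; 0.5 > 0.05
  r <- bh_fdr(c(0.03, 0.04), 0.05)
  expect_equal(r$reject, c(TRUE, TRUE))       # p_(2) = 0.04 <= 0.05
  r <- bh_fdr(rep(1, 5), 0.05)
  expect_equal(sum(r$reject), 0)
  expect_equal(r$p_adjusted, rep(1, 5))
  expect_equal(bh_fdr(numeric(0), 0.05)$reject, logical(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  # adjusted p-values agree with stats::p.adjust on random input
  set.seed(8)
  for (rep in 1:5) {
    p <- runif(50)^2
    expect_equal(bh_fdr(p, 0.05)$p_adjusted, p.adjust(p, "BH"),
                 tolerance = 1e-12)
  }
})

test_that("permutation null: determinism, bounds and the add-one floor", {
  fx <- make_vlsm_fixture(n = 30, seed = 23,
                          grid = reference_grid(c(12L, 12L, 12L), c(12, 12, 12)))
  spec <- design_spec("kps", n_permutations = 100, seed = 77)
  design <- build_design(fx$coh$clinical, spec)
  analyzed <- voxel_inclusion(fx$stack, 4)
  n1 <- permutation_null(fx$stack, design, analyzed, spec)
  n2 <- permutation_null(fx$stack, design, analyzed, spec)
  expect_identical(n1$p, n2$p)
  expect_identical(n1$threshold, n2$threshold)
  # p-values live in [1/(R+1), 1] and on the add-one lattice k/(R+1)
  expect_gte(min(n1$p), 1 / 101)
  expect_lte(max(n1$p), 1)
  expect_true(all(abs(n1$p * 101 - round(n1$p * 101)) < 1e-9))

  # a gross effect drives some voxel past every permutation: exact floor
  fx2 <- make_vlsm_fixture(n = 60, seed = 23, kps_effect = -60,
                           baseline_kps_sd = 8,
                           grid = reference_grid(c(12L, 12L, 12L), c(12, 12, 12)),
                           effect_radii_mm = c(30, 30, 30))
  spec2 <- design_spec("kps", n_permutations = 100, seed = 3)
  design2 <- build_design(fx2$coh$clinical, spec2)
  analyzed2 <- voxel_inclusion(fx2$stack, 4)
  null2 <- permutation_null(fx2$stack, design2, analyzed2, spec2)
  expect_equal(min(null2$p), 1 / 101)

  # p-resolution guard: fewer than 100 permutations is refused up front
  expect_error(design_spec("kps", n_permutations = 50), "100")
})

test_that("extract_roi limiting cases and conjunction rule", {
  fx <- make_vlsm_fixture(n = 40, seed = 37, kps_effect = -30,
                          grid = reference_grid(c(12L, 12L, 12L), c(12, 12, 12)),
                          effect_radii_mm = c(30, 30, 30))
  spec <- design_spec("kps", n_permutations = 150, seed = 9)
  design <- build_design(fx$coh$clinical, spec)
  analyzed <- voxel_inclusion(fx$stack, 4)
  sm <- fit_voxelwise_glm(fx$stack, design, analyzed)
  null <- permutation_null(fx$stack, design, analyzed, spec, statmap = sm)

  # alpha -> 1 with threshold rule disabled recovers the analyzed mask
  spec_all <- design_spec("kps", alpha = 0.9999, n_permutations = 150, seed = 9)
  roi_all <- extract_roi(sm, null, spec_all, use_threshold = FALSE)
  expect_identical(roi_all$voxels, sm$analyzed)

  # the conjunction ROI is a subset of both individual rules
  roi <- extract_roi(sm, null, spec, label = "ROI1", subgroup = "GBM")
  fdr_only <- extract_roi(sm, null, spec, use_threshold = FALSE)
  expect_true(all(roi$voxels <= fdr_only$voxels))
  expect_true(all(roi$voxels <= sm$analyzed))
  expect_equal(roi$provenance$label, "ROI1")
  expect_equal(roi$provenance$n_analyzed, length(sm$analyzed_idx))
})

test_that("maxstat mode gives brain-wise thresholds at least as strict", {
  fx <- make_vlsm_fixture(n = 40, seed = 41,
                          grid = reference_grid(c(12L, 12L, 12L), c(12, 12, 12)))
  specs <- lapply(c("pervoxel", "maxstat"), function(m)
    design_spec("kps", n_permutations = 120, seed = 13, threshold_mode = m))
  design <- build_design(fx$coh$clinical, specs[[1]])
  analyzed <- voxel_inclusion(fx$stack, 4)
  sm <- fit_voxelwise_glm(fx$stack, design, analyzed)
  nv <- permutation_null(fx$stack, design, analyzed, specs[[1]], statmap = sm)
  nm <- permutation_null(fx$stack, design, analyzed, specs[[2]], statmap = sm)
  expect_length(unique(nm$threshold), 1)            # one brain-wise value
  expect_true(all(nm$threshold >= nv$threshold - 1e-12))
  expect_true(all(nm$p >= nv$p - 1e-12))            # conservative
})

test_that("monotonicity: stronger KPS effect never shrinks mean ROI size", {
  # reduced-scale monotonicity property (8 seeds, small grid)
  sizes <- sapply(c(-10, -25, -40), function(eff) {
    mean(sapply(1:8, function(s) {
      coh <- generate_cohort(sim_config(
        grid = reference_grid(c(16L, 16L, 16L), c(8, 8, 8)),
        n_patients = 80, seed = s, kps_effect = eff,
        effect_radii_mm = c(24, 24, 24)))
      st <- build_stack(coh$masks, coh$clinical)
      res <- run_vlsm(st, coh$clinical,
                      design_spec("kps", n_permutations = 200, seed = 100 + s))
      sum(res$roi$voxels)
    }))
  })
  expect_true(all(diff(sizes) >= 0))
})

test_that("run_vlsm returns an empty ROI with a warning when nothing passes inclusion", {
  fx <- make_vlsm_fixture(n = 12, seed = 43,
                          grid = reference_grid(c(10L, 10L, 10L), c(16, 16, 16)))
  spec <- design_spec("kps", min_lesion_count = 6, n_permutations = 100, seed = 1)
  expect_warning(
    expect_warning(res <- run_vlsm(fx$stack, fx$coh$clinical, spec),
                   "no voxel"),
    "empty analyzed")
  expect_equal(sum(res$roi$voxels), 0)
})
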