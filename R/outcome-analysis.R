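# Risk stratification by ROI involvement and its statistical validation:
# Kaplan-Meier / log-rank, Cox hazard ratio, fixed-horizon survival ROC and
# cohort-characteristics tests. KM/log-rank/Cox are delegated to the
# `survival` package behind thin, contract-checked wrappers; the
# fixed-horizon ROC, chi-square and t-test wrappers are implemented here.

#' Assign high/low risk groups by ROI involvement
#'
#' A patient is high-risk when their lesion shares at least one voxel with
#' any of the supplied ROIs ("completely or partially overlapped"),
#' otherwise low-risk. Per-ROI overlap voxel counts are recorded; the total
#' count doubles as a continuous involvement marker for ROC analysis.
#'
#' @param masks list of [lesion_mask()] objects.
#' @param rois list of `roi_mask` objects on the same grid.
#' @return data.frame: patient_id, risk_group (`"high"`/`"low"`),
#'   overlapping_rois (comma-joined labels), total_overlap_voxels, plus one
#'   `overlap_<label>` count column per ROI.
#' @export
assign_risk_groups <- function(masks, rois) {
  if (!length(rois)) {
    warning("no ROIs supplied: all patients assigned low risk", call. = FALSE)
  }
  labels <- vapply(rois, function(r) r$label, character(1))
  rows <- lapply(masks, function(m) {
    counts <- vapply(rois, function(r) {
      if (!grid_equal(m$grid, r$grid))
        stop_grid_mismatch(r$grid, m$grid, m$patient_id)
      sum(m$voxels != 0L & r$voxels != 0L)
    }, numeric(1))
    hit <- counts >= 1
    df <- data.frame(patient_id = m$patient_id,
                     risk_group = if (any(hit)) "high" else "low",
                     overlapping_rois = paste(labels[hit], collapse = ","),
                     total_overlap_voxels = sum(counts),
                     stringsAsFactors = FALSE)
    for (i in seq_along(rois)) df[[paste0("overlap_", labels[i])]] <- counts[i]
    df
  })
  do.call(rbind, rows)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator (at tied times, events precede censorings).
#'
#' @param times positive survival/censoring times.
#' @param events 1 = death observed, 0 = censored.
#' @return object of class `km_curve`: data.frame `curve` with time,
#'   n_risk, n_event, n_censor, survival; plus `n`.
#' @export
km_estimate <- function(times, events) {
  check_surv_input(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      survival = fit$surv)
  structure(list(curve = curve, n = length(times)), class = "km_curve")
}

check_surv_input <- function(times, events, what = "survival input") {
  if (!length(times)) stop(what, ": empty input", call. = FALSE)
  if (length(times) != length(events))
    stop(what, ": times and events differ in length", call. = FALSE)
  if (any(times <= 0)) stop(what, ": times must be > 0", call. = FALSE)
  if (!all(events %in% c(0, 1)))
    stop(what, ": events must be 0/1", call. = FALSE)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 df and two-sided p, with
#' observed/expected event counts per group. Zero events overall returns
#' p = 1 with a warning.
#'
#' @param times_a,events_a group A survival data.
#' @param times_b,events_b group B survival data.
#' @return object of class `logrank_result`: `chisq`, `p`, `observed`,
#'   `expected` (length-2, A then B).
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  check_surv_input(times_a, events_a, "group A")
  check_surv_input(times_b, events_b, "group B")
  if (sum(events_a) + sum(events_b) == 0) {
    warning("no events in either group: log-rank undefined, p = 1",
            call. = FALSE)
    return(structure(list(chisq = 0, p = 1, observed = c(0, 0),
                          expected = c(0, 0)), class = "logrank_result"))
  }
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  grp <- factor(rep(c("A", "B"), c(length(times_a), length(times_b))))
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  structure(list(chisq = unname(sd$chisq),
                 p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 observed = unname(sd$obs), expected = unname(sd$exp)),
            class = "logrank_result")
}

#' Univariate Cox proportional-hazards ratio between risk groups
#'
#' Single-covariate partial-likelihood fit with Efron tie handling. The
#' reported hazard ratio is oriented low-risk vs high-risk, so a protective
#' low-risk group (longer survival) gives HR < 1 with a Wald 95% CI; the
#' reciprocal (high vs low) is also returned. Monotone likelihood (complete
#' separation of event times) is flagged and yields an unbounded CI.
#'
#' @param times,events survival data.
#' @param group character/factor of `"high"`/`"low"` (or any two levels;
#'   `reference` names the denominator level).
#' @param reference reference (denominator) group; default `"high"`.
#' @return object of class `cox_result`: `hr`, `ci` (length 2), `se`,
#'   `p`, `hr_reciprocal`, `orientation`, `flag_monotone`.
#' @export
cox_hazard_ratio <- function(times, events, group, reference = "high") {
  check_surv_input(times, events)
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2L)
    stop("group indicator must have exactly 2 levels, got: ",
         paste(lev, collapse = ", "), call. = FALSE)
  if (!reference %in% lev) reference <- lev[1]
  other <- setdiff(lev, reference)
  for (l in lev) if (sum(events[group == l]) < 1)
    stop("group `", l, "` has no events: Cox fit undefined", call. = FALSE)
  ind <- as.numeric(group == other)   # 1 = non-reference (e.g. low risk)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ ind, ties = "efron"),
    warning = function(w) invokeRestart("muffleWarning"))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  monotone <- !is.finite(beta) || !is.finite(se) || abs(beta) > 15
  ci <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
  if (monotone) ci <- c(0, Inf)
  structure(list(hr = exp(beta), ci = ci, se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 hr_reciprocal = exp(-beta),
                 orientation = paste0(other, " vs ", reference),
                 flag_monotone = monotone),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> HR (%s) = %.3f, 95%% CI %.3f-%.3f, p = %.4g%s\n",
              x$orientation, x$hr, x$ci[1], x$ci[2], x$p,
              if (x$flag_monotone) " [monotone likelihood]" else ""))
  invisible(x)
}

# all-pairs concordance AUC with ties counted 1/2, via the rank identity
auc_concordance <- function(marker_case, marker_control) {
  n1 <- length(marker_case); n0 <- length(marker_control)
  r <- rank(c(marker_case, marker_control))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fixed-horizon survival ROC
#'
#' Dichotomizes survival at a horizon: cases died by the horizon, controls
#' were followed beyond it, and patients censored before the horizon are
#' excluded (their status is unknown). AUC is the all-pairs concordance of
#' the marker (ties count 1/2, higher marker predicts death); the CI is a
#' seeded percentile bootstrap over the included patients.
#'
#' @param marker per-patient risk score (higher = worse expected outcome).
#' @param times,events survival data aligned with `marker`.
#' @param horizon evaluation time (> 0), same unit as `times`.
#' @param n_boot bootstrap replicates for the CI (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return object of class `time_roc_result`: `horizon`, `auc`, `ci`,
#'   `n_cases`, `n_controls`, `n_excluded_censored`.
#' @export
roc_at_horizon <- function(marker, times, events, horizon,
                           n_boot = 2000L, seed = 1L, conf = 0.95) {
  check_surv_input(times, events)
  if (length(marker) != length(times))
    stop("marker and survival data differ in length", call. = FALSE)
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  case <- times <= horizon & events == 1
  control <- times > horizon
  excluded <- times <= horizon & events == 0
  if (!any(case) || !any(control))
    stop(sprintf("no %s at horizon %g: ROC undefined",
                 if (!any(case)) "cases" else "controls", horizon),
         call. = FALSE)
  auc <- auc_concordance(marker[case], marker[control])

  status <- ifelse(case, 1L, ifelse(control, 0L, NA_integer_))
  inc <- which(!is.na(status))
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set_seed_strict(seed)
    boots <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      repeat {  # redraw resamples that lose a whole class
        s <- sample(inc, length(inc), replace = TRUE)
        if (any(status[s] == 1L) && any(status[s] == 0L)) break
      }
      boots[b] <- auc_concordance(marker[s][status[s] == 1L],
                                  marker[s][status[s] == 0L])
    }
    qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE, type = 7)
    ci <- c(min(qs[1], auc), max(qs[2], auc))
  }
  structure(list(horizon = horizon, auc = auc, ci = ci,
                 n_cases = sum(case), n_controls = sum(control),
                 n_excluded_censored = sum(excluded)),
            class = "time_roc_result")
}

#' @export
print.time_roc_result <- function(x, ...) {
  cat(sprintf("<time_roc_result> horizon %g: AUC = %.3f (95%% CI %.3f-%.3f), %d cases / %d controls, %d censored excluded\n",
              x$horizon, x$auc, x$ci[1], x$ci[2],
              x$n_cases, x$n_controls, x$n_excluded_censored))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction (the convention that reproduces published
#' cohort-characteristics tables), df = 1, two-sided p.
#'
#' @param table 2x2 integer matrix of counts.
#' @return list with `statistic`, `p`, `expected`.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal: chi-square undefined", call. = FALSE)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  statistic <- sum((table - expected)^2 / expected)
  list(statistic = statistic,
       p = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
       expected = expected)
}

#' Two-sample t-test
#'
#' Welch by default (`equal_variance = TRUE` for the pooled Student
#' flavor); two-sided. Degenerate zero-variance samples with equal means
#' return statistic 0, p = 1.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param equal_variance pooled-variance Student test instead of Welch.
#' @return list with `statistic`, `p`, `df`, `mean_x`, `mean_y`.
#' @export
two_sample_ttest <- function(x, y, equal_variance = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  res <- tryCatch(
    stats::t.test(x, y, var.equal = equal_variance),
    error = function(e) {
      if (grepl("essentially constant", conditionMessage(e)) &&
          isTRUE(all.equal(mean(x), mean(y))))
        return(list(statistic = c(t = 0), p.value = 1,
                    parameter = c(df = length(x) + length(y) - 2)))
      stop(e)
    })
  list(statistic = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), mean_x = mean(x), mean_y = mean(y))
}
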