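#' Descriptive summary of a set of shifts
#'
#' Mean, median, interquartile range (Q3 - Q1 with linear-interpolation,
#' type-7 quantiles) and range, the summary reported per axis and setup in
#' positioning-uncertainty tables.
#'
#' @param values numeric, length >= 2, finite.
#' @param quantile_type quantile algorithm passed to [stats::quantile()].
#' @return list of class `descriptive_summary`: `shift_range` (min, max),
#'   `mean`, `median`, `interquartile_range`, `n`.
#' @export
descriptive_stats <- function(values, quantile_type = 7) {
  if (length(values) < 2L || any(!is.finite(values)))
    stop("values must be >= 2 finite numbers", call. = FALSE)
  q <- quantile(values, probs = c(0.25, 0.75), names = FALSE,
                type = quantile_type)
  structure(list(shift_range = c(min(values), max(values)),
                 mean = mean(values), median = median(values),
                 interquartile_range = q[2] - q[1], n = length(values)),
            class = "descriptive_summary")
}

#' Bland-Altman agreement summary
#'
#' Mean of the paired differences, their sample standard deviation (n - 1
#' denominator) and the limits of agreement `mean +/- k * SD`. The nominal
#' 95% coverage factor is k = 1.96; k = 2 is the rounded convention some
#' published tables use and is available through the `k` argument.
#'
#' @param differences numeric, length >= 2.
#' @param k coverage factor.
#' @return list of class `bland_altman_summary`: `mean_of_deviations`,
#'   `standard_deviation`, `limit_upper`, `limit_lower`, `k`, `n`.
#' @export
bland_altman <- function(differences, k = 1.96) {
  if (length(differences) < 2L || any(!is.finite(differences)))
    stop("differences must be >= 2 finite numbers", call. = FALSE)
  m <- mean(differences)
  s <- sd(differences)
  structure(list(mean_of_deviations = m, standard_deviation = s,
                 limit_upper = m + k * s, limit_lower = m - k * s,
                 k = k, n = length(differences)),
            class = "bland_altman_summary")
}

#' One-sample t-test against a hypothesized mean
#'
#' Two-sided Student t-test of whether the mean shift differs from `mu0`
#' (default 0), as used to flag systematic positioning offsets.
#'
#' @param values numeric, length >= 2, not all equal to `mu0`.
#' @param mu0 hypothesized mean.
#' @return list of class `ttest_result`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `mu0`, `n`.
#' @export
one_sample_ttest <- function(values, mu0 = 0) {
  if (length(values) < 2L || any(!is.finite(values)))
    stop("values must be >= 2 finite numbers", call. = FALSE)
  if (sd(values) == 0)
    stop("degenerate sample: zero standard deviation", call. = FALSE)
  tt <- t.test(values, mu = mu0, alternative = "two.sided")
  structure(list(t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value = tt$p.value, mu0 = mu0, n = length(values)),
            class = "ttest_result")
}

#' Round half away from zero
#'
#' Fixed-precision rounding where ties go away from zero (2.745 -> 2.75,
#' -2.745 -> -2.75), the convention used for the reported error tables.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return numeric.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Quadrature total error
#'
#' Combines the registration algorithm's mean error (mRE) with the mean
#' positioning error of a setup (mPE) as `TE = sqrt(mRE^2 + mPE^2)`:
#' sign-insensitive, `TE >= max(|mRE|, |mPE|)` and
#' `TE <= |mRE| + |mPE|`.
#'
#' @param mre mean registration error (mm or degrees).
#' @param mpe mean positioning error (same units).
#' @return unrounded total error; report tables round it with
#'   [round_half_away()] to 2 decimals.
#' @export
total_error <- function(mre, mpe) {
  if (any(!is.finite(mre)) || any(!is.finite(mpe)))
    stop("mre and mpe must be finite", call. = FALSE)
  sqrt(mre^2 + mpe^2)
}

# map each shift component to its registration-error group
.mre_for_component <- function(component, registration_errors) {
  need <- c("xy_mm", "z_mm", "rot_deg")
  if (!all(need %in% names(registration_errors)))
    stop("registration_errors must provide xy_mm, z_mm and rot_deg",
         call. = FALSE)
  grp <- c(tx_mm = "xy_mm", ty_mm = "xy_mm", tz_mm = "z_mm",
           pitch_deg = "rot_deg", roll_deg = "rot_deg", yaw_deg = "rot_deg")
  unlist(registration_errors[grp[component]], use.names = FALSE)
}

.report_from_means <- function(means, registration_errors, digits = 2) {
  mre <- .mre_for_component(means$component, registration_errors)
  te_raw <- total_error(mre, means$mean)
  data.frame(component = means$component, setup = means$setup,
             mre = mre, mpe = means$mean, te_raw = te_raw,
             te = round_half_away(te_raw, digits))
}

#' Build a per-axis total-error report from a shift table
#'
#' For every shift component and setup, the mean positioning error (mPE) is
#' the signed mean shift; it is combined in quadrature with the registration
#' algorithm's mean error (mRE) for that component's group. The in-plane
#' translations x and y share one mRE, z has its own, and all three
#' rotations share one.
#'
#' @param shifts shift table `data.frame`
#'   (see [simulate_cohort_shifts()] / [read_shift_table()]).
#' @param registration_errors list with elements `xy_mm`, `z_mm`, `rot_deg`:
#'   the mean registration errors per group.
#' @param digits report rounding (half away from zero).
#' @return `data.frame` with columns `component`, `setup`, `mre`, `mpe`,
#'   `te_raw` (unrounded) and `te` (rounded).
#' @export
build_error_report <- function(shifts, registration_errors, digits = 2) {
  shifts <- .check_shift_table(shifts)
  comp <- .component_names()
  means <- do.call(rbind, lapply(split(shifts, shifts$setup), function(d)
    data.frame(component = comp, setup = d$setup[1],
               mean = vapply(comp, function(k) mean(d[[k]]), numeric(1)))))
  means <- means[order(match(means$component, comp), means$setup), ]
  rownames(means) <- NULL
  .report_from_means(means, registration_errors, digits)
}

#' Summarize a shift table per component and setup
#'
#' Descriptive statistics plus the one-sample t-test against zero, the
#' per-axis summary reported for each positioning setup.
#'
#' @param shifts shift table `data.frame`.
#' @return `data.frame` with columns `component`, `setup`, `n`, `min`,
#'   `max`, `mean`, `median`, `iqr`, `t_statistic`, `p_value`.
#' @export
summarize_shifts <- function(shifts) {
  shifts <- .check_shift_table(shifts)
  comp <- .component_names()
  out <- lapply(split(shifts, shifts$setup), function(d) {
    do.call(rbind, lapply(comp, function(k) {
      ds <- descriptive_stats(d[[k]])
      tt <- tryCatch(one_sample_ttest(d[[k]]),
                     error = function(e) list(t_statistic = NA_real_,
                                              p_value = NA_real_))
      data.frame(component = k, setup = d$setup[1], n = ds$n,
                 min = ds$shift_range[1], max = ds$shift_range[2],
                 mean = ds$mean, median = ds$median,
                 iqr = ds$interquartile_range,
                 t_statistic = tt$t_statistic, p_value = tt$p_value)
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$component, comp), out$setup), ]
  rownames(out) <- NULL
  out
}
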