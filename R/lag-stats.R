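#' Summarise replicate lag (and doubling) times for one condition
#'
#' @param lags Numeric vector of per-replicate lag times (hours); at least
#'   two finite values.
#' @param condition Condition label.
#' @param doublings Optional numeric vector of per-replicate doubling times.
#' @return A `condition_summary` with the replicate count, sample mean and
#'   sample standard deviation (n - 1 denominator) of each statistic.
#' @export
summarize_condition <- function(lags, condition, doublings = NULL) {
  lags <- lags[is.finite(lags)]
  if (length(lags) < 2L) {
    stop("condition '", condition,
         "': at least 2 finite lag values are required to form a summary")
  }
  out <- list(condition = condition, n = length(lags),
              mean_lag = mean(lags), sd_lag = stats::sd(lags),
              mean_doubling = NA_real_, sd_doubling = NA_real_)
  if (!is.null(doublings)) {
    doublings <- doublings[is.finite(doublings)]
    if (length(doublings) >= 2L) {
      out$mean_doubling <- mean(doublings)
      out$sd_doubling <- stats::sd(doublings)
    }
  }
  class(out) <- "condition_summary"
  out
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> '%s' (n = %d): lag %.3f (sd %.3f) h",
              x$condition, x$n, x$mean_lag, x$sd_lag))
  if (is.finite(x$mean_doubling)) {
    cat(sprintf(", doubling %.3f (sd %.3f) h", x$mean_doubling, x$sd_doubling))
  }
  cat("\n")
  invisible(x)
}

#' Lag-time difference between a control and a treatment condition
#'
#' The delta-lag statistic is the mean lag of the control minus the mean lag
#' of the treatment, so a positive value means the supplement shortened the
#' lag phase. Its uncertainty is the standard deviation of the estimated
#' difference between means,
#' \deqn{\sigma_{M_1 - M_2} = \sqrt{\sigma_1^2/n_1 + \sigma_2^2/n_2}}
#'
#' @param control,treatment `condition_summary` objects.
#' @return A `delta_lag` object with `delta_lag` (hours), `sd_diff` (hours),
#'   and — when filled in by [dunnett_many_to_one()] — `p_adjusted` and a
#'   `significance` category.
#' @export
delta_lag <- function(control, treatment) {
  stopifnot(inherits(control, "condition_summary"),
            inherits(treatment, "condition_summary"))
  structure(
    list(treatment = treatment$condition, control = control$condition,
         delta_lag = control$mean_lag - treatment$mean_lag,
         sd_diff = sqrt(control$sd_lag^2 / control$n +
                          treatment$sd_lag^2 / treatment$n),
         p_adjusted = NA_real_, significance = NA_character_),
    class = "delta_lag"
  )
}

#' @export
print.delta_lag <- function(x, ...) {
  cat(sprintf("Delta-lag %s vs control %s: %.2f (±%.2f) h",
              x$treatment, x$control, x$delta_lag, x$sd_diff))
  if (!is.na(x$p_adjusted)) {
    cat(sprintf("   adj. p = %.2g [%s]", x$p_adjusted, x$significance))
  }
  cat("\n")
  invisible(x)
}

#' Significance category from an adjusted p-value
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, `NS` above.
#'
#' @param p Adjusted p-value(s).
#' @return Character vector of categories.
#' @export
significance_category <- function(p) {
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
                ifelse(p <= 0.05, "*", "NS")))
}

#' Dunnett many-to-one comparisons against a control condition
#'
#' Fits a one-way ANOVA to the per-replicate values and tests every
#' treatment against the single control with Dunnett's procedure (two-sided,
#' family-wise adjusted over the K-1 comparisons, sharing the pooled ANOVA
#' error variance), via [multcomp::glht()].
#'
#' @param values Named list: one numeric vector of per-replicate values
#'   (lag or doubling times) per condition; every condition needs >= 2
#'   replicates.
#' @param control Name of the control condition (must be in `values`).
#' @return A data frame with one row per treatment: `condition`, `estimate`
#'   (control mean minus treatment mean), `p_adjusted`, `significance`.
#' @export
dunnett_many_to_one <- function(values, control) {
  if (!control %in% names(values)) {
    stop("control condition '", control, "' not present in the data")
  }
  if (any(vapply(values, length, 1L) < 2L)) {
    stop("every condition needs at least 2 replicate values")
  }
  conditions <- c(control, setdiff(names(values), control))
  df <- data.frame(
    value = unlist(values, use.names = FALSE),
    condition = factor(rep(names(values), lengths(values)),
                       levels = conditions)
  )
  fit <- stats::aov(value ~ condition, data = df)
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett"))
  test <- summary(glht)$test
  treatments <- conditions[-1]
  data.frame(
    condition = treatments,
    # glht estimates treatment - control; flip so positive = shorter lag
    estimate = -unname(test$coefficients),
    p_adjusted = pmin(1, unname(as.numeric(test$pvalues))),
    significance = significance_category(unname(as.numeric(test$pvalues))),
    stringsAsFactors = FALSE
  )
}

#' Full lag-phase comparison across a set of fitted wells
#'
#' Convenience wrapper tying the pipeline together: takes per-well logistic
#' fits, drops non-growing wells, extracts lag and doubling times, and
#' returns the per-treatment delta-lag table with propagated standard
#' deviations and Dunnett-adjusted p-values.
#'
#' @param fits List of `logistic_fit` objects carrying condition metadata.
#' @param control Control condition label.
#' @param threshold OD600 threshold for the lag-time definition.
#' @return A data frame with one row per treatment: sample sizes, mean lag
#'   times, `delta_lag_h`, `sd_diff_h`, `delta_doubling_h`,
#'   `p_adjusted`, `significance`.
#' @export
compare_lag_times <- function(fits, control, threshold = 0.01) {
  ok <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  fits <- fits[ok]
  if (length(fits) == 0L) stop("no converged fits to compare")
  conds <- vapply(fits, function(f) f$condition, "")
  if (!control %in% conds) stop("control condition '", control, "' has no converged wells")
  lags <- split(vapply(fits, lag_time, 1, threshold = threshold), conds)
  doublings <- split(vapply(fits, doubling_time, 1), conds)

  dunnett_lag <- dunnett_many_to_one(lags, control)
  ctrl_sum <- summarize_condition(lags[[control]], control,
                                  doublings[[control]])
  rows <- lapply(dunnett_lag$condition, function(cond) {
    trt_sum <- summarize_condition(lags[[cond]], cond, doublings[[cond]])
    d <- delta_lag(ctrl_sum, trt_sum)
    data.frame(
      treatment = cond, control = control,
      n_treat = trt_sum$n, n_ctrl = ctrl_sum$n,
      mean_lag_treat_h = trt_sum$mean_lag, mean_lag_ctrl_h = ctrl_sum$mean_lag,
      delta_lag_h = d$delta_lag, sd_diff_h = d$sd_diff,
      delta_doubling_h = ctrl_sum$mean_doubling - trt_sum$mean_doubling,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- dunnett_lag$p_adjusted
  out$significance <- dunnett_lag$significance
  out
}

#' Format a delta-lag estimate like a results table entry
#'
#' @param delta_lag_h Delta-lag estimate, hours.
#' @param sd_diff_h Standard deviation of the difference, hours.
#' @return Character, e.g. `"1.2 (±0.1)"`.
#' @export
format_delta_lag <- function(delta_lag_h, sd_diff_h) {
  sprintf("%.1f (±%.1f)", delta_lag_h, sd_diff_h)
}
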