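#' The logistic growth curve
#'
#' Population size at time `t` under logistic growth:
#' \deqn{N_t = K / [1 + ((K - N_0)/N_0) e^{-rt}]}
#' with carrying capacity `K`, initial size `N0` and intrinsic rate `r`
#' (per hour).
#'
#' @param t Time(s), hours.
#' @param K Carrying capacity (OD600 units), > 0.
#' @param N0 Initial population size (OD600 units), 0 < N0 < K.
#' @param r Intrinsic growth rate, per hour, > 0.
#' @return N_t on the OD600 scale.
#' @export
logistic_od <- function(t, K, N0, r) {
  K / (1 + ((K - N0) / N0) * exp(-r * t))
}

#' Closed-form lag time of a logistic curve
#'
#' The lag time is defined as the time at which the logistic curve reaches a
#' fixed OD600 threshold (default 0.01 on the background-subtracted scale).
#' Rearranging the logistic equation for `t` at `N_t = threshold` gives
#' \deqn{t = (-1/r)[\ln((K - N_t)/(K - N_0)) - \ln(N_t/N_0)]}
#' If the fitted `N0` already exceeds the threshold the formula yields a
#' negative lag, which is reported as-is so that lag differences between
#' conditions remain well defined.
#'
#' @inheritParams logistic_od
#' @param threshold OD600 threshold defining growth onset; must be < K.
#' @return Lag time in hours.
#' @export
logistic_lag_time <- function(K, N0, r, threshold = 0.01) {
  if (any(threshold >= K)) {
    stop("lag time undefined: threshold >= carrying capacity K, ",
         "the population never reaches the threshold")
  }
  (-1 / r) * (log((K - threshold) / (K - N0)) - log(threshold / N0))
}

#' Closed-form doubling time of a logistic curve
#'
#' Time for the population to grow from `N0` to `2 N0`, obtained by solving
#' the logistic equation at `N_t = 2 N0`:
#' \deqn{t = (-1/r)[\ln((K - 2N_0)/(K - N_0)) - \ln 2]}
#' In the early-growth limit `N0 << K` this approaches `ln(2)/r`.
#'
#' @inheritParams logistic_od
#' @return Doubling time in hours.
#' @export
logistic_doubling_time <- function(K, N0, r) {
  if (any(2 * N0 >= K)) {
    stop("doubling time undefined: 2*N0 >= K, ",
         "the population cannot double under the fitted model")
  }
  (-1 / r) * (log((K - 2 * N0) / (K - N0)) - log(2))
}

# Starting values for the optimizer: K from the curve maximum; r and N0 from
# a log-linear regression over the exponential window (readings between 10%
# and 70% of the maximum), whose slope estimates r and whose intercept
# extrapolates the effective initial size. Falls back to the smallest
# positive reading and the median rising log-slope on curves with no clear
# exponential window.
logistic_start <- function(time, od600) {
  K0 <- max(od600)
  sel <- which(od600 > 0.1 * K0 & od600 < 0.7 * K0)
  r0 <- NA_real_
  N00 <- NA_real_
  if (length(sel) >= 2L) {
    cf <- stats::coef(stats::lm(log(od600[sel]) ~ time[sel]))
    r0 <- cf[2]
    N00 <- exp(cf[1])
  }
  if (!is.finite(r0) || r0 <= 0) {
    logod <- log(pmax(od600, K0 * 1e-4))
    slopes <- diff(logod) / diff(time)
    r0 <- stats::median(slopes[is.finite(slopes) & slopes > 0])
    if (!is.finite(r0) || r0 <= 0) r0 <- 0.5
  }
  if (!is.finite(N00) || N00 <= 0) {
    pos <- od600[od600 > 0]
    N00 <- if (length(pos)) max(min(pos), 1e-6) else 1e-6
  }
  N00 <- min(max(N00, 1e-10), K0 / 10)
  c(K = unname(K0), N0 = unname(N00), r = unname(r0))
}

#' Fit the logistic growth model to a growth curve
#'
#' Least-squares fit of [logistic_od()] to background-corrected OD600
#' readings. Parameters are estimated on the log scale (log K, log N0,
#' log r) with the Levenberg-Marquardt algorithm, which enforces positivity
#' without hard bounds. Wells whose dynamic range (max - min OD600) falls
#' below `growth_floor` carry no usable kinetic signal: they are marked
#' non-converged and flagged non-growing rather than force-fitted.
#'
#' @param x A `growth_curve` (see [subtract_background()]), or a numeric
#'   vector of times (with `od600` supplied).
#' @param ... Passed to methods.
#' @return An object of class `logistic_fit` with components `K`, `N0`, `r`,
#'   `sse`, `converged`, `non_growing`, `fitted`, plus the input data and
#'   well metadata. Use [coef()], [predict()], [lag_time()],
#'   [doubling_time()], [summary()], [plot()] on it.
#' @examples
#' tt <- seq(0, 24, by = 1 / 3)
#' od <- logistic_od(tt, K = 0.5, N0 = 1e-4, r = 0.8)
#' fit <- fit_logistic(tt, od)
#' coef(fit)
#' lag_time(fit)
#' doubling_time(fit)
#' @export
fit_logistic <- function(x, ...) UseMethod("fit_logistic")

#' @rdname fit_logistic
#' @param od600 Background-corrected OD600 readings (default method).
#' @param growth_floor Minimum OD600 dynamic range for a well to count as
#'   growing (default 0.02).
#' @param control Optimizer control list; see [minpack.lm::nls.lm.control()].
#' @export
fit_logistic.default <- function(x, od600, growth_floor = 0.02,
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = 1000, ftol = 1e-10),
                                 ...) {
  time <- as.numeric(x)
  od600 <- as.numeric(od600)
  if (length(time) != length(od600)) stop("time and od600 lengths differ")
  if (length(time) < 4L) stop("logistic fit needs at least 4 data points")

  out <- structure(
    list(K = NA_real_, N0 = NA_real_, r = NA_real_, sse = NA_real_,
         converged = FALSE, non_growing = FALSE,
         fitted = rep(NA_real_, length(time)),
         time = time, od600 = od600,
         well_id = NA_character_, condition = NA_character_,
         replicate_index = NA_integer_, threshold_floor = growth_floor,
         call = match.call()),
    class = "logistic_fit"
  )

  if (diff(range(od600)) < growth_floor) {
    out$non_growing <- TRUE
    return(out)
  }

  start <- logistic_start(time, od600)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      od600 ~ exp(lK) / (1 + ((exp(lK) - exp(lN0)) / exp(lN0)) *
                           exp(-exp(lr) * time)),
      data = list(od600 = od600, time = time),
      start = list(lK = log(unname(start["K"])),
                   lN0 = log(unname(start["N0"])),
                   lr = log(unname(start["r"]))),
      control = control
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(out)

  est <- exp(stats::coef(fit))
  out$K <- unname(est["lK"])
  out$N0 <- unname(est["lN0"])
  out$r <- unname(est["lr"])
  out$fitted <- logistic_od(time, out$K, out$N0, out$r)
  out$sse <- sum((od600 - out$fitted)^2)
  out$converged <- out$N0 < out$K && out$r > 0 &&
    (out$K - out$N0) >= growth_floor
  if (!out$converged) out$non_growing <- TRUE
  out
}

#' @rdname fit_logistic
#' @export
fit_logistic.growth_curve <- function(x, ...) {
  fit <- fit_logistic.default(x$time, x$od600, ...)
  fit$well_id <- x$well_id
  fit$condition <- x$condition
  fit$replicate_index <- x$replicate_index
  if (isTRUE(x$non_growing)) {
    fit$non_growing <- TRUE
    fit$converged <- FALSE
  }
  fit
}

#' @export
coef.logistic_fit <- function(object, ...) {
  c(K = object$K, N0 = object$N0, r = object$r)
}

#' @export
fitted.logistic_fit <- function(object, ...) object$fitted

#' @export
residuals.logistic_fit <- function(object, ...) object$od600 - object$fitted

#' Predict OD600 from a fitted logistic model
#'
#' @param object A converged `logistic_fit`.
#' @param newdata Optional data frame with a `time` column (hours), or a
#'   numeric vector of times; defaults to the fitted times.
#' @param ... Unused.
#' @return Predicted OD600 values.
#' @export
predict.logistic_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  t <- if (is.null(newdata)) {
    object$time
  } else if (is.numeric(newdata)) {
    newdata
  } else {
    newdata$time
  }
  logistic_od(t, object$K, object$N0, object$r)
}

#' Lag time of a fitted growth curve
#'
#' @param object A converged `logistic_fit`.
#' @param threshold OD600 threshold defining growth onset (default 0.01 on
#'   the background-subtracted scale).
#' @param ... Unused.
#' @return Lag time in hours (may be negative if the fitted N0 exceeds the
#'   threshold).
#' @seealso [logistic_lag_time()] for the closed form on raw parameters.
#' @export
lag_time <- function(object, ...) UseMethod("lag_time")

#' @rdname lag_time
#' @export
lag_time.logistic_fit <- function(object, threshold = 0.01, ...) {
  if (!object$converged) stop("lag time undefined for a non-converged fit")
  logistic_lag_time(object$K, object$N0, object$r, threshold)
}

#' Doubling time of a fitted growth curve
#'
#' @param object A converged `logistic_fit`.
#' @param ... Unused.
#' @return Doubling time in hours.
#' @seealso [logistic_doubling_time()] for the closed form on raw parameters.
#' @export
doubling_time <- function(object, ...) UseMethod("doubling_time")

#' @rdname doubling_time
#' @export
doubling_time.logistic_fit <- function(object, ...) {
  if (!object$converged) stop("doubling time undefined for a non-converged fit")
  logistic_doubling_time(object$K, object$N0, object$r)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic growth fit")
  if (!is.na(x$well_id)) {
    cat(sprintf(" — well %s, condition '%s'", x$well_id, x$condition))
  }
  cat("\n")
  if (x$non_growing) {
    cat("  non-growing well (dynamic range below floor or fit failed)\n")
  } else if (!x$converged) {
    cat("  fit did not converge\n")
  } else {
    cat(sprintf("  K = %.4g  N0 = %.4g  r = %.4g /h   (SSE %.3g)\n",
                x$K, x$N0, x$r, x$sse))
  }
  invisible(x)
}

#' @export
summary.logistic_fit <- function(object, threshold = 0.01, ...) {
  out <- list(fit = object, threshold = threshold,
              lag = NA_real_, doubling = NA_real_,
              rmse = sqrt(mean(residuals(object)^2)))
  if (object$converged) {
    if (threshold < object$K) {
      out$lag <- lag_time(object, threshold)
    }
    if (2 * object$N0 < object$K) out$doubling <- doubling_time(object)
  }
  class(out) <- "summary.logistic_fit"
  out
}

#' @export
print.summary.logistic_fit <- function(x, ...) {
  print(x$fit)
  if (x$fit$converged) {
    cat(sprintf("  lag time (OD %.3g): %.3f h   doubling time: %.3f h   RMSE %.2g\n",
                x$threshold, x$lag, x$doubling, x$rmse))
  }
  invisible(x)
}

#' Plot a fitted logistic growth curve
#'
#' Observed OD600 readings with the fitted logistic overlaid; the lag-time
#' threshold crossing is marked when it lies inside the observed span.
#'
#' @param x A `logistic_fit`.
#' @param threshold OD600 threshold marked on the plot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.logistic_fit <- function(x, threshold = 0.01, ...) {
  graphics::plot(x$time, x$od600, xlab = "time (h)", ylab = "OD600",
                 pch = 16, cex = 0.6, ...)
  if (x$converged) {
    tt <- seq(min(x$time), max(x$time), length.out = 200)
    graphics::lines(tt, predict(x, tt), col = "steelblue", lwd = 2)
    lag <- lag_time(x, threshold)
    if (lag >= min(x$time) && lag <= max(x$time)) {
      graphics::abline(v = lag, h = threshold, lty = 3, col = "grey40")
    }
  }
  invisible(x)
}

#' Simulate noisy replicate curves from a fitted model
#'
#' Draws `nsim` replicate OD600 series from the fitted logistic curve with
#' additive Gaussian measurement noise at the residual standard deviation.
#'
#' @param object A converged `logistic_fit`.
#' @param nsim Number of replicate series.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with one column per simulated replicate, rows
#'   matching the fitted time points.
#' @export
simulate.logistic_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from a non-converged fit")
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(object$sse / length(object$time))
  mu <- object$fitted
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
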