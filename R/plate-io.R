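#' Read a plate layout map
#'
#' A plate layout maps each well to its experimental condition. It is a
#' plain CSV with columns `well`, `condition` and optionally `supplement`
#' and `concentration_molar`.
#'
#' @param path Path to the layout CSV.
#' @return A data frame of class `plate_layout` with one row per well.
#' @export
read_plate_layout <- function(path) {
  layout <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_plate_layout(layout)
}

#' Coerce a data frame to a plate layout
#'
#' @param layout Data frame with at least `well` and `condition` columns;
#'   `supplement` and `concentration_molar` are optional.
#' @return The validated data frame with class `plate_layout`.
#' @export
as_plate_layout <- function(layout) {
  layout <- as.data.frame(layout)
  required <- c("well", "condition")
  missing <- setdiff(required, names(layout))
  if (length(missing) > 0L) {
    stop("plate layout is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(layout$well)) {
    stop("plate layout lists well(s) more than once: ",
         paste(unique(layout$well[duplicated(layout$well)]), collapse = ", "))
  }
  if (!"supplement" %in% names(layout)) layout$supplement <- NA_character_
  if (!"concentration_molar" %in% names(layout)) {
    layout$concentration_molar <- NA_real_
  }
  class(layout) <- c("plate_layout", "data.frame")
  layout
}

new_plate_series <- function(well_id, time, absorbance, condition,
                             replicate_index) {
  if (length(time) < 4L) {
    stop("well ", well_id, ": fewer than 4 time points")
  }
  if (any(!is.finite(absorbance))) {
    stop("well ", well_id, ": non-finite absorbance values")
  }
  if (any(diff(time) <= 0)) {
    stop("well ", well_id, ": time points are not strictly increasing ",
         "(duplicated or unsorted readings)")
  }
  structure(
    list(well_id = well_id, time = as.numeric(time),
         absorbance = as.numeric(absorbance),
         condition = condition, replicate_index = as.integer(replicate_index)),
    class = "plate_series"
  )
}

#' @export
print.plate_series <- function(x, ...) {
  cat(sprintf("<plate_series> well %s, condition '%s' (replicate %d): %d readings, %.2f-%.2f h\n",
              x$well_id, x$condition, x$replicate_index,
              length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Read a plate-reader export
#'
#' Parses a plate-reader absorbance table in either the long dialect
#' (columns `well`, `time_h`, `absorbance`) or the wide dialect (first
#' column `time_h`, one column per well) and attaches condition metadata
#' from a plate layout. Times are kept in hours internally; exports with
#' minute-resolution clocks can be ingested with `time_unit = "minutes"`.
#'
#' @param path Path to the CSV file.
#' @param dialect `"long"` or `"wide"`.
#' @param layout A `plate_layout` (see [read_plate_layout()]) covering every
#'   well present in the file.
#' @param time_unit Unit of the time column; `"hours"` (default),
#'   `"minutes"` or `"seconds"`. Converted to hours on ingest.
#' @return A list of `plate_series`, one per well, each sorted by time.
#' @export
read_plate_table <- function(path, dialect = c("long", "wide"), layout,
                             time_unit = c("hours", "minutes", "seconds")) {
  dialect <- match.arg(dialect)
  time_unit <- match.arg(time_unit)
  layout <- as_plate_layout(layout)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)

  if (dialect == "long") {
    needed <- c("well", "time_h", "absorbance")
    if (!all(needed %in% names(raw))) {
      stop("long dialect requires columns: ", paste(needed, collapse = ", "))
    }
    long <- raw[needed]
  } else {
    if (names(raw)[1] != "time_h") {
      stop("wide dialect requires the first column to be 'time_h'")
    }
    wells <- names(raw)[-1]
    long <- data.frame(
      well = rep(wells, each = nrow(raw)),
      time_h = rep(raw$time_h, times = length(wells)),
      absorbance = unlist(raw[-1], use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }

  div <- switch(time_unit, hours = 1, minutes = 60, seconds = 3600)
  long$time_h <- long$time_h / div

  unknown <- setdiff(unique(long$well), layout$well)
  if (length(unknown) > 0L) {
    stop("well(s) absent from the plate layout: ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(long[c("well", "time_h")])) {
    stop("duplicated (well, time) reading(s) in ", path)
  }

  wells <- intersect(layout$well, unique(long$well))
  series <- vector("list", length(wells))
  names(series) <- wells
  rep_counter <- integer(0)
  for (w in wells) {
    rows <- long[long$well == w, , drop = FALSE]
    rows <- rows[order(rows$time_h), , drop = FALSE]
    cond <- layout$condition[match(w, layout$well)]
    rep_counter[cond] <- if (is.na(rep_counter[cond][1])) 1L else rep_counter[cond] + 1L
    series[[w]] <- new_plate_series(
      well_id = w, time = rows$time_h, absorbance = rows$absorbance,
      condition = cond, replicate_index = rep_counter[[cond]]
    )
  }
  series
}

#' Calibrate plate-reader absorbance to cuvette-equivalent OD600
#'
#' Microtitre-plate absorbance readings depend on the optical path length of
#' the liquid column; multiplying by an instrument-specific factor converts
#' them to the OD600 scale of a 1-cm cuvette. The default factor, 3.8603,
#' corresponds to 150 ul culture under a hexadecane overlay.
#'
#' @param series A `plate_series`, or a list of them.
#' @param factor Positive multiplicative calibration factor.
#' @return The series with every absorbance multiplied by `factor`.
#' @export
calibrate_absorbance <- function(series, factor = 3.8603) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop("calibration factor must be a single positive number")
  }
  if (is.list(series) && !inherits(series, "plate_series")) {
    return(lapply(series, calibrate_absorbance, factor = factor))
  }
  series$absorbance <- series$absorbance * factor
  series
}

#' Subtract the per-well background absorbance
#'
#' The background is the mean absorbance during the non-growth phase, when
#' the signal is stable (by default 2-8 h after inoculation), computed for
#' each well individually and subtracted from that well's readings. Negative
#' corrected values are retained: clipping at zero would bias the fitted
#' initial population size upwards.
#'
#' @param series A `plate_series` (calibrated), or a list of them.
#' @param window Length-2 numeric, `(t_start, t_end)` in hours delimiting the
#'   non-growth phase; must contain at least two readings.
#' @return A `growth_curve`: the background-corrected series with the
#'   estimated `background_value` attached.
#' @export
subtract_background <- function(series, window = c(2, 8)) {
  if (is.list(series) && !inherits(series, "plate_series") &&
      !inherits(series, "growth_curve")) {
    return(lapply(series, subtract_background, window = window))
  }
  if (length(window) != 2L || !all(is.finite(window)) || window[1] > window[2]) {
    stop("background window must be a finite (t_start, t_end) pair")
  }
  values <- if (inherits(series, "growth_curve")) series$od600 else series$absorbance
  in_window <- series$time >= window[1] & series$time <= window[2]
  if (sum(in_window) < 2L) {
    stop("background window [", window[1], ", ", window[2],
         "] h contains fewer than 2 readings for well ", series$well_id)
  }
  background <- mean(values[in_window])
  structure(
    list(well_id = series$well_id, time = series$time,
         od600 = values - background,
         condition = series$condition,
         replicate_index = series$replicate_index,
         background_value = background,
         non_growing = isTRUE(series$non_growing)),
    class = "growth_curve"
  )
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> well %s, condition '%s' (replicate %d)\n",
              x$well_id, x$condition, x$replicate_index))
  cat(sprintf("  %d readings over %.2f-%.2f h; background %.4f; max OD600 %.4f%s\n",
              length(x$time), min(x$time), max(x$time), x$background_value,
              max(x$od600), if (isTRUE(x$non_growing)) " [non-growing]" else ""))
  invisible(x)
}

#' Trim a growth curve to its growth span
#'
#' Restricts the curve to the contiguous stretch from the global minimum to
#' the global maximum OD600 — the span the logistic fit should see. If the
#' maximum precedes the minimum the well never grew; it is flagged
#' `non_growing` and returned untrimmed.
#'
#' @param curve A `growth_curve`.
#' @return The trimmed `growth_curve` (or the flagged original).
#' @export
trim_to_growth_span <- function(curve) {
  if (is.list(curve) && !inherits(curve, "growth_curve")) {
    return(lapply(curve, trim_to_growth_span))
  }
  stopifnot(inherits(curve, "growth_curve"))
  if (length(curve$od600) == 0L) stop("empty growth curve")
  i_min <- which.min(curve$od600)
  i_max <- which.max(curve$od600)
  if (i_max < i_min) {
    curve$non_growing <- TRUE
    return(curve)
  }
  keep <- seq.int(i_min, i_max)
  curve$time <- curve$time[keep]
  curve$od600 <- curve$od600[keep]
  curve
}

#' Convert growth curves to a tidy data frame
#'
#' @param curves A `growth_curve` or list of them.
#' @return A data frame with columns well, condition, replicate, time_h,
#'   od600, background.
#' @export
growth_curve_table <- function(curves) {
  if (inherits(curves, "growth_curve")) curves <- list(curves)
  do.call(rbind, lapply(curves, function(cv) {
    data.frame(well = cv$well_id, condition = cv$condition,
               replicate = cv$replicate_index, time_h = cv$time,
               od600 = cv$od600, background = cv$background_value,
               stringsAsFactors = FALSE)
  }))
}
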