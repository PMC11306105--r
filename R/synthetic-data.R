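#' Configuration for a synthetic plate-reader experiment
#'
#' Describes the conditions on a simulated 96-well plate: one row per
#' condition with its true logistic parameters and replicate count, plus
#' the instrument model (additive Gaussian read noise, constant background
#' offset, calibration factor, 20-min read cycle over 30 h by default).
#'
#' Default true parameters emulate a marine heterotroph growing on 1 mM
#' glucose: K = 0.5 OD, r = 0.8 /h, and a small effective N0 (the fitted
#' initial size absorbs physiological lag, so it sits well below the
#' nominal inoculum density), giving control lag times around 14 h with a
#' flat pre-growth phase across the 2-8 h background window.
#'
#' @param conditions Data frame with columns `condition`, `K`, `N0`, `r`,
#'   `n_rep` (replicates per condition, >= 2).
#' @param control Label of the control condition (default: first row).
#' @param noise_sd SD of additive Gaussian measurement noise, OD600 units
#'   (default 0.003).
#' @param background_level Constant background absorbance added to every
#'   reading before the calibration division (default 0.15).
#' @param calibration_factor Instrument calibration factor (default 3.8603);
#'   simulated raw values are divided by it, so re-calibrating on ingest
#'   recovers the OD600 scale.
#' @param sampling_interval Hours between reads (default 1/3, i.e. 20 min).
#' @param duration Total duration in hours (default 30).
#' @param seed Integer seed; a fixed seed makes the output bit-reproducible.
#' @return A `plate_config`.
#' @export
plate_config <- function(conditions = default_plate_conditions(),
                         control = conditions$condition[1],
                         noise_sd = 0.003, background_level = 0.15,
                         calibration_factor = 3.8603,
                         sampling_interval = 1 / 3, duration = 30,
                         seed = 1L) {
  stopifnot(all(c("condition", "K", "N0", "r", "n_rep") %in% names(conditions)))
  if (any(conditions$K <= 0 | conditions$N0 <= 0 | conditions$r <= 0)) {
    stop("true K, N0 and r must all be positive")
  }
  if (any(conditions$n_rep < 2L)) stop("each condition needs >= 2 replicates")
  if (!control %in% conditions$condition) stop("unknown control condition")
  structure(list(conditions = conditions, control = control,
                 noise_sd = noise_sd, background_level = background_level,
                 calibration_factor = calibration_factor,
                 sampling_interval = sampling_interval, duration = duration,
                 seed = as.integer(seed)),
            class = "plate_config")
}

#' Default synthetic plate conditions
#'
#' A water control and a supplemented treatment sharing K and r (supplements
#' shorten the lag but leave the growth rate unchanged), the treatment's N0
#' adjusted via [lag_effect_via_n0()] to inject a 2.5 h lag shortening —
#' the largest effect size of interest — at n = 4 replicates each.
#'
#' @param delta_lag_h Injected lag shortening of the treatment, hours.
#' @param n_rep Replicates per condition.
#' @return Data frame suitable for [plate_config()].
#' @export
default_plate_conditions <- function(delta_lag_h = 2.5, n_rep = 4L) {
  K <- 0.5; r <- 0.8; N0_ctrl <- 1e-7
  N0_trt <- lag_effect_via_n0(N0_ctrl, delta_lag_h, r = r, K = K)
  data.frame(
    condition = c("control", "treatment"),
    K = K, N0 = c(N0_ctrl, N0_trt), r = r, n_rep = as.integer(n_rep),
    stringsAsFactors = FALSE
  )
}

#' Shift a lag time by adjusting the initial population size
#'
#' Supplements shorten the lag phase without changing the growth rate; under
#' the logistic model that is an increase of the effective initial size N0.
#' Solving the closed-form lag expression for the N0 that moves the lag by
#' `-target_delta_lag` gives, with q = N0/(K - N0) * exp(r * delta),
#' N0' = qK / (1 + q). The returned N0' satisfies
#' `lag(K, N0', r) = lag(K, N0, r) - target_delta_lag` exactly.
#'
#' @param base_N0 Baseline initial size (OD600).
#' @param target_delta_lag Desired lag shortening, hours (negative values
#'   prolong the lag).
#' @param r,K Logistic rate and carrying capacity.
#' @param threshold Lag-defining OD600 threshold; N0' must stay below it.
#' @return Adjusted initial size N0'.
#' @export
lag_effect_via_n0 <- function(base_N0, target_delta_lag, r, K,
                              threshold = 0.01) {
  stopifnot(base_N0 > 0, base_N0 < K, threshold < K)
  q <- base_N0 / (K - base_N0) * exp(r * target_delta_lag)
  N0_new <- q * K / (1 + q)
  if (N0_new >= threshold) {
    stop("infeasible lag shift: adjusted N0 (", signif(N0_new, 3),
         ") reaches the lag threshold ", threshold)
  }
  N0_new
}

#' Simulate a plate-reader experiment with known ground truth
#'
#' For every well, raw absorbance readings are generated as
#' `(logistic(t; K, N0, r) + background_level + N(0, noise_sd)) /
#' calibration_factor`, sampled every `sampling_interval` hours over
#' `duration`. Ground-truth lag, doubling and delta-lag values are computed
#' from the noiseless closed forms on the true parameters. All wells draw
#' from one seeded random stream in fixed well order, so an identical seed
#' reproduces the plate exactly.
#'
#' @param config A [plate_config()].
#' @param mode `"n0"` (default) keeps the generative model inside the
#'   logistic family; `"time_shift"` instead shifts each treatment curve
#'   rigidly in time by the condition's lag offset relative to the first
#'   condition — a model-misspecification stressor.
#' @return A list of class `synthetic_plate`:
#'   `plate` (long data frame well/time_h/absorbance), `layout`
#'   (a `plate_layout`), `truth` (per-condition data frame with true
#'   parameters, `true_lag_h`, `true_doubling_h`, `true_delta_lag_h` vs the
#'   control) and the `config`.
#' @export
simulate_plate <- function(config, mode = c("n0", "time_shift")) {
  stopifnot(inherits(config, "plate_config"))
  mode <- match.arg(mode)
  set.seed(config$seed)
  tt <- seq(0, config$duration, by = config$sampling_interval)
  conds <- config$conditions

  truth <- data.frame(
    condition = conds$condition, K = conds$K, N0 = conds$N0, r = conds$r,
    true_lag_h = logistic_lag_time(conds$K, conds$N0, conds$r),
    true_doubling_h = logistic_doubling_time(conds$K, conds$N0, conds$r),
    stringsAsFactors = FALSE
  )
  ctrl_lag <- truth$true_lag_h[truth$condition == config$control]
  truth$true_delta_lag_h <- ctrl_lag - truth$true_lag_h

  rows <- list()
  layout_rows <- list()
  for (i in seq_len(nrow(conds))) {
    shift <- if (mode == "time_shift") {
      truth$true_delta_lag_h[i]
    } else 0
    N0_i <- if (mode == "time_shift") conds$N0[1] else conds$N0[i]
    for (j in seq_len(conds$n_rep[i])) {
      well <- sprintf("%s%d", LETTERS[i], j)
      od <- logistic_od(tt + shift, conds$K[i], N0_i, conds$r[i])
      raw <- (od + config$background_level +
                stats::rnorm(length(tt), 0, config$noise_sd)) /
        config$calibration_factor
      rows[[well]] <- data.frame(well = well, time_h = tt, absorbance = raw,
                                 stringsAsFactors = FALSE)
      layout_rows[[well]] <- data.frame(well = well,
                                        condition = conds$condition[i],
                                        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(plate = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         layout = as_plate_layout(do.call(rbind, layout_rows)),
         truth = truth, config = config),
    class = "synthetic_plate"
  )
}

#' @export
print.synthetic_plate <- function(x, ...) {
  cat(sprintf("<synthetic_plate> %d wells x %d reads (%s conditions; seed %d)\n",
              length(unique(x$plate$well)),
              length(unique(x$plate$time_h)),
              nrow(x$truth), x$config$seed))
  print(x$truth[c("condition", "true_lag_h", "true_doubling_h",
                  "true_delta_lag_h")])
  invisible(x)
}

#' Write a simulated plate to CSV
#'
#' Emits the same long/wide dialects [read_plate_table()] consumes, for
#' file-based round trips.
#'
#' @param plate A `synthetic_plate` (or its `$plate` data frame).
#' @param path Output CSV path.
#' @param dialect `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  df <- if (inherits(plate, "synthetic_plate")) plate$plate else plate
  if (dialect == "long") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    wells <- unique(df$well)
    times <- sort(unique(df$time_h))
    wide <- data.frame(time_h = times)
    for (w in wells) {
      sub <- df[df$well == w, ]
      wide[[w]] <- sub$absorbance[match(times, sub$time_h)]
    }
    utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Run the full lag-phase pipeline on a simulated plate
#'
#' Calibrate, background-subtract, trim, fit and compare: the in-memory
#' equivalent of the file-based workflow, returning the delta-lag table for
#' the plate's treatments against its control.
#'
#' @param sim A `synthetic_plate` from [simulate_plate()].
#' @param background_window Background window passed to
#'   [subtract_background()].
#' @param threshold Lag-defining OD600 threshold.
#' @return The [compare_lag_times()] data frame.
#' @export
analyze_synthetic_plate <- function(sim, background_window = c(2, 8),
                                    threshold = 0.01) {
  stopifnot(inherits(sim, "synthetic_plate"))
  series <- list()
  rep_counter <- integer(0)
  for (w in unique(sim$plate$well)) {
    sub <- sim$plate[sim$plate$well == w, ]
    cond <- sim$layout$condition[match(w, sim$layout$well)]
    rep_counter[cond] <- if (is.na(rep_counter[cond][1])) 1L else rep_counter[cond] + 1L
    series[[w]] <- new_plate_series(w, sub$time_h, sub$absorbance, cond,
                                    rep_counter[[cond]])
  }
  curves <- lapply(series, function(s) {
    trim_to_growth_span(subtract_background(
      calibrate_absorbance(s, sim$config$calibration_factor),
      window = background_window))
  })
  fits <- lapply(curves, fit_logistic)
  compare_lag_times(fits, control = sim$config$control, threshold = threshold)
}

#' Simulate a feature table with known truth labels
#'
#' Generates negative-binomial counts around lognormal gene means, a set of
#' rRNA genes at strongly elevated abundance (mimicking an undepleted
#' library), and a set of differentially expressed genes whose `log2fc` and
#' `padj` columns are assigned to pass the standard thresholds while all
#' other genes are assigned values that fail them; DE gene means are floored
#' high enough that they also clear the abundance filter. Truth labels
#' (`is_de_truth`, `is_rrna`) and a random `kegg_metabolic` tag are
#' attached.
#'
#' @param n_genes,n_samples Table dimensions.
#' @param rrna_fraction Fraction of genes flagged rRNA (default 0.05).
#' @param de_fraction Fraction of non-rRNA genes that are DE (default 0.1).
#' @param de_log2fc Absolute log2 fold change assigned to DE genes
#'   (default 1.0); random sign.
#' @param de_padj Adjusted p assigned to DE genes (default 1e-4).
#' @param seed Integer seed; fixed seed gives an identical table.
#' @return A [feature_table()]; truth labels live in `$genes`.
#' @export
simulate_feature_table <- function(n_genes = 1000, n_samples = 6,
                                   rrna_fraction = 0.05, de_fraction = 0.1,
                                   de_log2fc = 1.0, de_padj = 1e-4,
                                   seed = 1L) {
  stopifnot(rrna_fraction >= 0, rrna_fraction <= 1,
            de_fraction >= 0, de_fraction <= 1)
  set.seed(as.integer(seed))
  gene_id <- sprintf("gene_%04d", seq_len(n_genes))
  length_bp <- sample(500:3000, n_genes, replace = TRUE)
  base_mean <- stats::rlnorm(n_genes, meanlog = log(100), sdlog = 1.5)

  n_rrna <- round(rrna_fraction * n_genes)
  is_rrna <- c(rep(TRUE, n_rrna), rep(FALSE, n_genes - n_rrna))
  n_de <- round(de_fraction * sum(!is_rrna))
  is_de <- rep(FALSE, n_genes)
  is_de[sample(which(!is_rrna), n_de)] <- TRUE

  base_mean[is_rrna] <- base_mean[is_rrna] * 100
  base_mean[is_de] <- pmax(base_mean[is_de], 500)

  counts <- matrix(stats::rnbinom(n_genes * n_samples,
                                  mu = rep(base_mean, n_samples), size = 20),
                   nrow = n_genes,
                   dimnames = list(gene_id,
                                   sprintf("sample_%d", seq_len(n_samples))))

  log2fc <- stats::runif(n_genes, -0.4, 0.4)
  padj <- stats::runif(n_genes, 0.1, 1)
  log2fc[is_de] <- sample(c(-1, 1), n_de, replace = TRUE) * de_log2fc
  padj[is_de] <- de_padj
  log2fc[is_rrna] <- NA_real_
  padj[is_rrna] <- NA_real_

  genes <- data.frame(
    gene_id = gene_id, length = length_bp,
    log2fc = log2fc, padj = padj,
    is_rrna = is_rrna, is_de_truth = is_de,
    kegg_metabolic = stats::runif(n_genes) < 0.2,
    stringsAsFactors = FALSE
  )
  feature_table(genes, counts)
}
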