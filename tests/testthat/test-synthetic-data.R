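test_that("noiseless, unit-factor simulation reproduces the logistic exactly", {
  conds <- data.frame(condition = c("ctrl", "trt"), K = 0.5,
                      N0 = c(1e-5, 1e-4), r = 0.8, n_rep = 2L)
  cfg <- plate_config(conds, noise_sd = 0, background_level = 0,
                      calibration_factor = 1, seed = 1)
  sim <- simulate_plate(cfg)
  tt <- unique(sim$plate$time_h)
  a1 <- sim$plate[sim$plate$well == "A1", ]
  expect_equal(a1$absorbance, logistic_od(tt, 0.5, 1e-5, 0.8))
  b2 <- sim$plate[sim$plate$well == "B2", ]
  expect_equal(b2$absorbance, logistic_od(tt, 0.5, 1e-4, 0.8))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  s1 <- simulate_plate(plate_config(seed = 33))
  s2 <- simulate_plate(plate_config(seed = 33))
  expect_identical(s1$plate, s2$plate)
  s3 <- simulate_plate(plate_config(seed = 34))
  expect_false(identical(s1$plate, s3$plate))

  f1 <- simulate_feature_table(seed = 8)
  f2 <- simulate_feature_table(seed = 8)
  expect_identical(f1, f2)

  # byte-identical CSV from the same seed
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_plate_csv(s1, p1); write_plate_csv(s2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("ground truth equals the closed forms on the true parameters", {
  cfg <- plate_config(seed = 2)
  sim <- simulate_plate(cfg)
  with(sim$truth, {
    expect_equal(true_lag_h, logistic_lag_time(K, N0, r))
    expect_equal(true_doubling_h, logistic_doubling_time(K, N0, r))
  })
  ctrl <- sim$truth[sim$truth$condition == "control", ]
  expect_equal(sim$truth$true_delta_lag_h,
               ctrl$true_lag_h - sim$truth$true_lag_h)
  expect_equal(sim$truth$true_delta_lag_h[2], 2.5)
})

test_that("lag effects injected through N0 shift lag but not doubling time", {
  K <- 0.5; N0 <- 1e-4; r <- 0.8; thr <- 0.01
  # zero target returns the same N0
  expect_equal(lag_effect_via_n0(N0, 0, r, K, thr), N0)

  n0p <- lag_effect_via_n0(N0, 1.0, r, K, thr)
  expect_equal(logistic_lag_time(K, n0p, r, thr),
               logistic_lag_time(K, N0, r, thr) - 1.0)
  # agreement with numeric root-finding on the lag definition
  target_lag <- logistic_lag_time(K, N0, r, thr) - 1.0
  n0_root <- stats::uniroot(function(x) logistic_lag_time(K, x, r, thr) - target_lag,
                            c(1e-10, thr * 0.999), tol = 1e-14)$root
  expect_equal(n0p, n0_root, tolerance = 1e-8)

  # doubling time is essentially unchanged while N0 << K
  expect_equal(logistic_doubling_time(K, n0p, r),
               logistic_doubling_time(K, N0, r), tolerance = 1e-3)

  # negative target prolongs the lag
  slower <- lag_effect_via_n0(N0, -2, r, K, thr)
  expect_lt(slower, N0)

  # infeasible shift: N0 would reach the threshold
  expect_error(lag_effect_via_n0(N0, 10, r, K, thr), "infeasible")
})

test_that("simulated plates round-trip through the CSV readers", {
  cfg <- plate_config(seed = 12)
  sim <- simulate_plate(cfg)
  lp <- tempfile(fileext = ".csv"); wp <- tempfile(fileext = ".csv")
  write_plate_csv(sim, lp, "long")
  write_plate_csv(sim, wp, "wide")
  from_long <- read_plate_table(lp, "long", sim$layout)
  from_wide <- read_plate_table(wp, "wide", sim$layout)
  expect_identical(names(from_long), names(from_wide))
  for (w in names(from_long)) {
    expect_equal(from_long[[w]]$absorbance, from_wide[[w]]$absorbance)
  }
  expect_equal(from_long$A1$absorbance,
               sim$plate$absorbance[sim$plate$well == "A1"])
})

test_that("the full pipeline recovers an injected lag shift from files", {
  sim <- simulate_plate(plate_config(seed = 40))
  lp <- tempfile(fileext = ".csv")
  write_plate_csv(sim, lp, "long")
  series <- read_plate_table(lp, "long", sim$layout)
  curves <- lapply(calibrate_absorbance(series, sim$config$calibration_factor),
                   function(s) trim_to_growth_span(subtract_background(s)))
  fits <- lapply(curves, fit_logistic)
  res <- compare_lag_times(fits, control = "control")
  expect_equal(res$delta_lag_h, 2.5, tolerance = 0.1)
  expect_lte(res$p_adjusted, 0.001)
})

test_that("time-shift mode provides a model-misspecification stressor", {
  sim <- simulate_plate(plate_config(seed = 3), mode = "time_shift")
  res <- analyze_synthetic_plate(sim)
  # a rigid 2.5 h shift is still recovered approximately by the logistic fit
  expect_equal(res$delta_lag_h, 2.5, tolerance = 0.25)
})

test_that("simulated feature tables honour their truth construction", {
  ft <- simulate_feature_table(n_genes = 400, rrna_fraction = 0.05,
                               de_fraction = 0.1, seed = 6)
  g <- ft$genes
  expect_equal(sum(g$is_rrna), 20)
  expect_equal(sum(g$is_de_truth), round(0.1 * 380))
  expect_false(any(g$is_rrna & g$is_de_truth))
  # assigned statistics respect the thresholds by construction
  expect_true(all(abs(g$log2fc[g$is_de_truth]) >= 0.585))
  expect_true(all(g$padj[g$is_de_truth] <= 0.05))
  ok_non_de <- !g$is_de_truth & !g$is_rrna
  expect_true(all(abs(g$log2fc[ok_non_de]) < 0.585))
  expect_true(all(g$padj[ok_non_de] > 0.05))

  # no DE genes -> de_filter returns the empty set
  null_ft <- simulate_feature_table(n_genes = 200, de_fraction = 0, seed = 7)
  expect_equal(nrow(de_filter(remove_rrna(null_ft))$genes), 0)
})
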