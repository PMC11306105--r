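# Shared fixture builders: everything is generated in code at test time.

make_series <- function(well = "A1", time = c(0, 2, 4, 6, 8, 10),
                        absorbance = rep(0.05, length(time)),
                        condition = "control", replicate = 1L) {
  growthlag:::new_plate_series(well, time, absorbance, condition, replicate)
}

# A three-well long-format plate table plus its layout, written to temp CSVs.
write_demo_plate <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("plate")
    dir.create(dir)
  }
  times <- c(0, 1, 2, 3, 4)
  wells <- c("A1", "A2", "B1")
  long <- data.frame(
    well = rep(wells, each = length(times)),
    time_h = rep(times, times = length(wells)),
    absorbance = c(0.05, 0.06, 0.08, 0.12, 0.2,
                   0.05, 0.07, 0.09, 0.13, 0.21,
                   0.04, 0.05, 0.05, 0.06, 0.07)
  )
  long_path <- file.path(dir, "long.csv")
  wide_path <- file.path(dir, "wide.csv")
  utils::write.csv(long, long_path, row.names = FALSE, quote = FALSE)
  wide <- data.frame(time_h = times)
  for (w in wells) wide[[w]] <- long$absorbance[long$well == w]
  utils::write.csv(wide, wide_path, row.names = FALSE, quote = FALSE)
  layout <- as_plate_layout(data.frame(
    well = wells, condition = c("treated", "treated", "control")
  ))
  list(long = long_path, wide = wide_path, layout = layout, data = long)
}

# Noiseless logistic growth curve wrapped as a growth_curve object.
make_growth_curve <- function(K = 0.5, N0 = 1e-4, r = 0.8,
                              time = seq(0, 24, by = 1 / 3),
                              condition = "control", well = "A1",
                              replicate = 1L, noise_sd = 0) {
  od <- logistic_od(time, K, N0, r)
  if (noise_sd > 0) od <- od + stats::rnorm(length(time), 0, noise_sd)
  structure(
    list(well_id = well, time = time, od600 = od, condition = condition,
         replicate_index = replicate, background_value = 0,
         non_growing = FALSE),
    class = "growth_curve"
  )
}
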