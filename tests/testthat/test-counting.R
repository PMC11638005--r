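# Brightness calibration, extrapolation, stoichiometry KDE and periodicity.

test_that("backward extrapolation reproduces the line through the first 4 frames", {
  expect_equal(initial_intensity(c(100, 90, 80, 70)), 100)
  expect_equal(
    initial_intensity(data.frame(frame = 1:4, intensity = c(90, 80, 70, 60))),
    100)
  expect_equal(initial_intensity(rep(42, 10)), 42)
})

test_that("extrapolation matches a brute-force normal-equations solution", {
  set.seed(31)
  for (i in 1:50) {
    y <- rnorm(4, 200, 40)
    f0 <- sample(0:4, 1)
    x <- f0 + 0:3
    # normal equations, solved directly
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    got <- initial_intensity(data.frame(frame = x, intensity = y))
    expect_lt(abs(got - beta[1]) / max(abs(beta[1]), 1e-12), 1e-9)
  }
})

test_that("short or late-starting tracks are rejected for counting", {
  expect_error(initial_intensity(c(10, 9, 8)), "too short")
  expect_error(
    initial_intensity(data.frame(frame = 5:9, intensity = rep(1, 5))),
    "after the allowed initial window")
})

test_that("stoichiometry is the initial intensity over the calibrated brightness", {
  cal <- structure(list(brightness_pe = 56), class = "brightness_calibration")
  expect_equal(stoichiometry(rep(280, 4), cal), 5.0)
  expect_equal(stoichiometry(rep(0, 4), cal), 0.0)
  expect_equal(stoichiometry(rep(616, 4), cal), 11.0)
})

steps_table <- function(values, n_tracks = NULL, n_frames = 900) {
  # one track per value, sitting at that intensity through the terminal third
  if (is.null(n_tracks)) n_tracks <- length(values)
  do.call(rbind, lapply(seq_len(n_tracks), function(i)
    data.frame(track_id = i, frame = 600:899,
               intensity = values[(i - 1) %% length(values) + 1])))
}

test_that("calibration returns exact brightness for clean terminal steps", {
  cal <- calibrate_brightness(steps_table(56, n_tracks = 5))
  expect_equal(cal$brightness_pe, 56)
  expect_equal(cal$uncertainty_pe, 0)
})

test_that("calibration picks the dominant step height in a 1x/2x mixture", {
  set.seed(32)
  vals <- c(rep(56, 30), rep(112, 10)) + rnorm(40, 0, 2)
  cal <- calibrate_brightness(steps_table(vals))
  expect_lt(abs(cal$brightness_pe - 56), 5)
})

test_that("too few terminal steps is an explicit failure", {
  tab <- data.frame(track_id = 1, frame = 895:899, intensity = 56)
  expect_error(calibrate_brightness(tab), "calibration failed")
})

test_that("the stoichiometry KDE is a normalized density with peaks where the data are", {
  d1 <- stoichiometry_kde(5)
  expect_equal(d1$kde_grid[which.max(d1$kde_density)], 5,
               tolerance = 0.05)
  expect_error(stoichiometry_kde(5, kernel_width = -1), "positive")

  d2 <- stoichiometry_kde(c(rep(5, 30), rep(10, 30)))
  pk <- find_kde_peaks(d2)
  expect_equal(pk, c(5, 10), tolerance = 0.05)
  dens_at <- function(x) d2$kde_density[which.min(abs(d2$kde_grid - x))]
  expect_equal(dens_at(5), dens_at(10), tolerance = 1e-3)  # grid quantization

  for (d in list(d1, d2)) {
    grid <- d$kde_grid
    integral <- sum(diff(grid) *
                    (head(d$kde_density, -1) + tail(d$kde_density, -1)) / 2)
    expect_equal(integral, 1, tolerance = 1e-6)
  }
})

test_that("peak finding uses the strict-interior rule", {
  # monotone-decreasing density (all mass at the grid origin): no interior peak
  d <- stoichiometry_kde(0)
  expect_identical(length(find_kde_peaks(d)), 0L)
})

test_that("periodicity from consecutive peak intervals: mode and degenerate CI", {
  set.seed(33)
  per <- periodicity(list(c(5, 10, 15)), mean_stoich = 7.5, n_boot = 200)
  expect_equal(per$intervals$interval, c(5, 5))
  expect_equal(per$mode, 5, tolerance = 0.05)
  expect_equal(per$kde2_width, 0.7 * sqrt(7.5 / 2))

  single <- periodicity(list(c(3, 7)), mean_stoich = 5, n_boot = 50)
  expect_equal(single$mode, 4, tolerance = 0.05)
  expect_equal(unname(single$ci95["lo"]), unname(single$ci95["hi"]))

  expect_error(periodicity(list(5), mean_stoich = 5), ">= 2 peaks")
})

test_that("weighted interval mode matches direct grid evaluation and is order/scale invariant", {
  intervals <- c(4, 4, 4, 9)
  mean_stoich <- 6
  # package: peaks at cumulative positions give consecutive intervals 4,4,4,9
  peaks <- cumsum(c(2, intervals))
  set.seed(34)
  per <- periodicity(list(peaks), mean_stoich = mean_stoich, n_boot = 50)
  expect_equal(per$intervals$interval, intervals)

  # independent direct evaluation of the weighted KDE mode (scaled weights)
  bw <- 0.7 * sqrt(mean_stoich / length(intervals))
  grid <- seq(0, max(intervals) + 3 * bw, by = bw / 20)
  w <- 10 / sqrt(intervals)   # uniform rescaling must not matter
  dens <- sapply(grid, function(g) sum(w * dnorm(g, intervals, bw)))
  expect_equal(per$mode, grid[which.max(dens)])
  expect_equal(per$mode, 4, tolerance = 0.1)

  # interval ordering must not matter
  set.seed(34)
  per2 <- periodicity(list(rev(peaks)), mean_stoich = mean_stoich,
                      n_boot = 50)
  expect_equal(per2$mode, per$mode)
})

test_that("bootstrap CI covers the true periodicity in most simulated repeats", {
  set.seed(35)
  covered <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    # several acquisitions per repeat, as in a pyrenoid population
    pk <- lapply(1:6, function(a) {
      stoich <- sample(c(5, 10, 15), 120, replace = TRUE,
                       prob = c(0.6, 0.3, 0.1)) + rnorm(120, 0, 0.15)
      find_kde_peaks(stoichiometry_kde(stoich))
    })
    per <- periodicity(pk, mean_stoich = 7.5, n_boot = 200)
    if (per$ci95["lo"] <= 5 && 5 <= per$ci95["hi"]) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.9)
})

test_that("the counting pipeline recovers the true unit for a range of oligomer sizes", {
  set.seed(36)
  for (unit in c(2, 5, 8)) {
    tab <- mixture_track_table(n_acq = 1, n_per_acq = 120,
                               weights = 1, unit_stoichiometry = unit)
    rep <- run_counting_pipeline(tab, n_boot = 50)
    top_peak <- rep$peaks[which.max(
      rep$distribution$kde_density[match(
        rep$peaks, rep$distribution$kde_grid)])]
    expect_equal(top_peak, unit, tolerance = 0.35 / unit)
  }
})

test_that("pipeline errors are explicit and stage-labelled", {
  expect_error(run_counting_pipeline(list()), "empty input")
  short <- data.frame(track_id = 1, frame = 0:2, intensity = c(3, 2, 1))
  expect_error(run_counting_pipeline(short), "\\[calibration\\]")
})
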