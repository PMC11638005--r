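# Photobleaching trace and population simulator.

cfg900 <- acquisition_config()

test_that("degenerate traces behave exactly: empty, and forced immediate bleach", {
  p0 <- quiet_pentamer_params()
  expect_identical(simulate_trace(p0, cfg900, 0), rep(0, 900))

  p1 <- simulation_params(multiple_weights = 1, bleach_prob = 1,
                          noise_sd_pe = 0)
  tr <- simulate_trace(p1, cfg900, 5)
  expect_equal(tr[1], 5 * 56)
  expect_true(all(tr[-1] == 0))
})

test_that("unbleached fraction follows the geometric survival law", {
  set.seed(41)
  p <- simulation_params(multiple_weights = 1, bleach_prob = 0.01,
                         noise_sd_pe = 0)
  n_rep <- 10000
  frames_checked <- c(1, 51, 101, 301, 601)  # 1-based indices of frames 0,50,...
  acc <- matrix(0, n_rep, length(frames_checked))
  for (r in seq_len(n_rep))
    acc[r, ] <- simulate_trace(p, cfg900, 5)[frames_checked] / p$brightness_pe
  expected <- 5 * 0.99^(frames_checked - 1)
  # Monte-Carlo tolerance: 5 sigma of the mean of n_rep binomial counts
  tol <- 5 * sqrt(5 * 0.25 / n_rep)
  expect_true(all(abs(colMeans(acc) - expected) < tol))
})

test_that("noiseless traces are non-increasing", {
  set.seed(42)
  p <- quiet_pentamer_params(noise = 0)
  for (i in 1:50) {
    tr <- simulate_trace(p, cfg900, sample(1:12, 1))
    expect_true(all(diff(tr) <= 0))
  }
})

test_that("a seeded population is bit-reproducible", {
  p <- simulation_params(n_complexes = 25, seed = 99)
  pop1 <- simulate_population(p, cfg900)
  pop2 <- simulate_population(p, cfg900)
  expect_identical(pop1$traces, pop2$traces)
  expect_identical(pop1$truth, pop2$truth)
  expect_identical(pop1$bleach_frames, pop2$bleach_frames)
})

test_that("subunit counts follow unit x multiple with the requested weights", {
  p <- simulation_params(multiple_weights = 1, detection_fraction = 1,
                         n_complexes = 200, seed = 7)
  pop <- simulate_population(p, cfg900)
  expect_true(all(pop$truth$subunits == 5))
  expect_true(all(pop$truth$tagged == 5))

  w <- c(0.6, 0.25, 0.1, 0.05)
  p2 <- simulation_params(multiple_weights = w, n_complexes = 10000,
                          seed = 8)
  pop2 <- simulate_population(p2, cfg900)
  freq <- tabulate(pop2$truth$subunits / 5, nbins = 4) / 10000
  # binomial 4-sigma band per class
  expect_true(all(abs(freq - w) < 4 * sqrt(w * (1 - w) / 10000)))
  expect_true(all(pop2$truth$tagged <= pop2$truth$subunits))
})

test_that("ground-truth bleach frames are within the acquisition", {
  p <- simulation_params(n_complexes = 30, seed = 5, bleach_prob = 0.02)
  cfg <- acquisition_config(n_frames = 100)
  pop <- simulate_population(p, cfg)
  for (b in pop$bleach_frames) expect_true(all(b >= 1))
})

test_that("a rendered spot's disc sum recovers its trace value", {
  cfg <- acquisition_config(n_frames = 8, image_shape = c(40L, 40L))
  p <- simulation_params(multiple_weights = 1, bleach_prob = 1e-6,
                         noise_sd_pe = 0, n_complexes = 1, seed = 1)
  pop <- simulate_population(p, cfg)
  for (sigma in c(1.0, 1.5)) {
    r <- render_image_stack(pop, cfg, psf_sigma_px = sigma,
                            background_pe = 0,
                            positions = data.frame(spot_id = 1, row = 20.3,
                                                   col = 19.6))
    si <- summed_intensity(r$stack[, , 1], c(20.3, 19.6))
    expect_gte(si$summed_intensity, 0.98 * pop$traces[[1]][1])
  }
})

test_that("an untagged population renders as pure background", {
  cfg <- acquisition_config(n_frames = 8, image_shape = c(40L, 40L))
  p <- simulation_params(multiple_weights = 1, detection_fraction = 0,
                         noise_sd_pe = 0, n_complexes = 2, seed = 2)
  pop <- simulate_population(p, cfg)
  r <- render_image_stack(pop, cfg, background_pe = 7)
  expect_true(all(r$stack == 7))
})

test_that("spots must fit inside the image", {
  cfg <- acquisition_config(n_frames = 8, image_shape = c(40L, 40L))
  p <- simulation_params(multiple_weights = 1, n_complexes = 1, seed = 3)
  pop <- simulate_population(p, cfg)
  expect_error(
    render_image_stack(pop, cfg,
                       positions = data.frame(spot_id = 1, row = 45, col = 2)),
    "outside image bounds")
})

test_that("TIFF export round-trips photoelectron values within quantization", {
  cfg <- acquisition_config(n_frames = 8, image_shape = c(32L, 32L))
  p <- simulation_params(multiple_weights = 1, n_complexes = 1, seed = 4,
                         noise_sd_pe = 0)
  pop <- simulate_population(p, cfg)
  r <- render_image_stack(pop, cfg, background_pe = 5)
  path <- tempfile(fileext = ".tif")
  write_stack_tiff(r$stack, path, pe_per_count = 0.05)
  back <- read_stack_tiff(path)
  expect_equal(dim(back), dim(r$stack))
  expect_lt(max(abs(back - r$stack)), 0.05)  # half a count either way
})
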