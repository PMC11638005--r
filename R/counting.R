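# Molecular counting: single-fluorophore brightness calibration from
# terminal blink steps, backward extrapolation of initial intensities,
# kernel-density stoichiometry distributions, peak finding, and inference of
# the oligomer periodicity from weighted inter-peak intervals.

# Normalize counting input to a track table. Accepts a list of numeric
# trace vectors (frames 0-based from the start of illumination) or a data
# frame with track_id, frame, intensity (optionally intensity_pe) and an
# optional acquisition column.
as_track_table <- function(x) {
  if (is.data.frame(x)) {
    for (alias in c("intensity_pe", "summed_intensity"))
      if (alias %in% names(x) && !"intensity" %in% names(x))
        names(x)[names(x) == alias] <- "intensity"
    req <- c("track_id", "frame", "intensity")
    missing_cols <- setdiff(req, names(x))
    if (length(missing_cols) > 0)
      stop("track table is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    for (cl in c("frame", "intensity"))
      if (!is.numeric(x[[cl]]))
        stop("track table column '", cl, "' must be numeric")
    if (!"acquisition" %in% names(x)) x$acquisition <- 1L
    return(x[order(x$acquisition, x$track_id, x$frame), , drop = FALSE])
  }
  if (is.list(x)) {
    if (length(x) == 0) stop("empty input: no tracks or traces supplied")
    tabs <- lapply(seq_along(x), function(i) {
      tr <- x[[i]]
      stopifnot(is.numeric(tr))
      data.frame(track_id = i, frame = seq_along(tr) - 1L, intensity = tr,
                 acquisition = 1L)
    })
    return(do.call(rbind, tabs))
  }
  stop("unsupported input: expected a track data frame or a list of traces")
}

#' Calibrate single-fluorophore brightness from terminal blink steps
#'
#' After sufficient photobleaching only step-like blinking of the last
#' remaining fluorophore is observed at the end of each track; the modal
#' integrated intensity of those steps estimates the characteristic
#' single-molecule brightness. Candidate steps are harvested in two passes
#' from detections in the final `terminal_frac` of the acquisition: a noise
#' floor of 3 sigma (sigma estimated from the sub-zero terminal intensities)
#' removes fully bleached frames, a provisional KDE mode is computed from
#' the remainder, and the refined step set keeps intensities at most twice
#' the provisional brightness (i.e. tracks decayed to their last one or two
#' fluorophores). The calibration is the KDE mode of the refined steps; the
#' uncertainty is their median absolute deviation (scaled, comparable to a
#' +/- spread).
#'
#' @param tracks Track table or list of traces (see
#'   [run_counting_pipeline()] for formats).
#' @param n_frames Total frames in the acquisition; inferred from the data
#'   when `NULL`.
#' @param min_steps Minimum number of usable terminal steps (default 20);
#'   fewer is an error, never a silent default.
#' @param terminal_frac Fraction of the acquisition treated as terminal
#'   (default 1/3).
#' @return An object of class `brightness_calibration`: list with
#'   `brightness_pe`, `uncertainty_pe`, `n_steps_used`, `step_intensities`.
#' @examples
#' p <- simulation_params(n_complexes = 60, seed = 2)
#' pop <- simulate_population(p, acquisition_config())
#' calibrate_brightness(pop$traces)
#' @export
calibrate_brightness <- function(tracks, n_frames = NULL, min_steps = 20,
                                 terminal_frac = 1 / 3) {
  tab <- as_track_table(tracks)
  if (is.null(n_frames)) n_frames <- max(tab$frame) + 1L
  stopifnot(n_frames >= 8, terminal_frac > 0, terminal_frac < 1)
  x <- tab$intensity[tab$frame >= (1 - terminal_frac) * n_frames]
  if (length(x) == 0)
    stop("brightness calibration failed: no detections in the terminal ",
         round(terminal_frac * 100), "% of the acquisition")
  neg <- x[x < 0]
  sigma0 <- if (length(neg) > 0) sqrt(mean(neg^2)) else 0
  cand <- x[x > 3 * sigma0]
  if (length(cand) < min_steps)
    stop("brightness calibration failed: only ", length(cand),
         " terminal step candidates above the noise floor (",
         signif(3 * sigma0, 3), " pe); need at least ", min_steps)
  provisional <- kde_mode(cand)
  steps <- cand[cand <= 2 * provisional]
  if (length(steps) < min_steps)
    stop("brightness calibration failed: only ", length(steps),
         " steps below 2x the provisional brightness (",
         signif(provisional, 4), " pe); need at least ", min_steps)
  structure(
    list(brightness_pe = kde_mode(steps),
         uncertainty_pe = mad(steps),
         n_steps_used = length(steps),
         step_intensities = steps),
    class = "brightness_calibration"
  )
}

#' @export
print.brightness_calibration <- function(x, ...) {
  cat(sprintf(
    "Single-fluorophore brightness: %.1f +/- %.1f photoelectrons/frame (n = %d steps)\n",
    x$brightness_pe, x$uncertainty_pe, x$n_steps_used))
  invisible(x)
}

#' Initial intensity by backward linear extrapolation
#'
#' Ordinary least-squares line through the first four (frame, intensity)
#' points of a track, evaluated at frame 0 (the start of laser exposure).
#' This undoes the photobleaching that occurs during the first frames, so
#' the result may exceed the first measured value.
#'
#' @param track Numeric trace vector (frames 0-based) or data frame with
#'   `frame` and `intensity` columns.
#' @param start_frame_limit Tracks first detected after this frame are
#'   rejected: bleaching before first detection would bias the count.
#' @return Extrapolated intensity at frame 0, photoelectrons/frame.
#' @examples
#' initial_intensity(data.frame(frame = 1:4, intensity = c(90, 80, 70, 60)))
#' # 100: the line through the points, evaluated at frame 0
#' @export
initial_intensity <- function(track, start_frame_limit = 4) {
  if (is.numeric(track) && is.null(dim(track)))
    track <- data.frame(frame = seq_along(track) - 1L, intensity = track)
  stopifnot(all(c("frame", "intensity") %in% names(track)))
  track <- track[order(track$frame), , drop = FALSE]
  if (nrow(track) < 4)
    stop("track too short for 4-frame extrapolation (length ",
         nrow(track), ")")
  if (track$frame[1] > start_frame_limit)
    stop("track starts at frame ", track$frame[1],
         ", after the allowed initial window (frame ", start_frame_limit, ")")
  fit <- lm(intensity ~ frame, data = track[1:4, ])
  unname(coef(fit)[1])
}

#' Stoichiometry of one track
#'
#' The extrapolated initial intensity divided by the calibrated
#' single-fluorophore brightness: the estimated number of tagged molecules
#' in the complex. Not rounded.
#'
#' @param track As in [initial_intensity()].
#' @param cal A `brightness_calibration` (or a bare positive number).
#' @param start_frame_limit Passed to [initial_intensity()].
#' @return Estimated molecule count (float).
#' @export
stoichiometry <- function(track, cal, start_frame_limit = 4) {
  b <- if (inherits(cal, "brightness_calibration")) cal$brightness_pe else cal
  stopifnot(is.numeric(b), length(b) == 1, b > 0)
  initial_intensity(track, start_frame_limit) / b
}

#' Kernel-density stoichiometry distribution
#'
#' Gaussian KDE of the per-track molecule counts with a fixed kernel SD
#' (default 0.7 molecules, reflecting the background-noise contribution to
#' a single stoichiometry estimate), evaluated on a grid from 0 to the
#' maximum plus three kernel widths with spacing `kernel_width / 20` and
#' renormalized to integrate to 1 over the grid.
#'
#' @param stoichs Numeric vector of per-track stoichiometries.
#' @param kernel_width Gaussian kernel SD in molecules.
#' @return An object of class `stoichiometry_distribution`: list with
#'   `stoichiometries`, `kde_grid`, `kde_density`, `kernel_width`.
#' @examples
#' d <- stoichiometry_kde(c(rep(5, 20), rep(10, 20)))
#' find_kde_peaks(d)  # peaks at 5 and 10
#' @export
stoichiometry_kde <- function(stoichs, kernel_width = 0.7) {
  stopifnot(is.numeric(stoichs), length(stoichs) >= 1,
            all(is.finite(stoichs)))
  if (!is.numeric(kernel_width) || length(kernel_width) != 1 ||
      kernel_width <= 0)
    stop("kernel_width must be a positive number")
  grid <- seq(0, max(stoichs) + 3 * kernel_width, by = kernel_width / 20)
  dens <- wkde_density(stoichs, kernel_width, grid)
  dens <- dens / trapezoid_integral(grid, dens)
  structure(
    list(stoichiometries = stoichs, kde_grid = grid, kde_density = dens,
         kernel_width = kernel_width),
    class = "stoichiometry_distribution"
  )
}

#' @export
print.stoichiometry_distribution <- function(x, ...) {
  pk <- find_kde_peaks(x)
  cat("Stoichiometry distribution:", length(x$stoichiometries),
      "tracks, kernel width", x$kernel_width, "molecules\n")
  cat("  peaks at:", paste(signif(pk, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.stoichiometry_distribution <- function(x, ...) {
  plot(x$kde_grid, x$kde_density, type = "l",
       xlab = "stoichiometry (molecules)", ylab = "probability density", ...)
  pk <- find_kde_peaks(x)
  abline(v = pk, lty = 3, col = "grey40")
  invisible(x)
}

#' Peaks of a stoichiometry distribution
#'
#' Strict interior local maxima of the KDE curve whose prominence is at
#' least `prominence_frac` of the maximum density, in ascending order.
#'
#' @param dist A `stoichiometry_distribution`.
#' @param prominence_frac Minimum prominence as a fraction of the highest
#'   density.
#' @return Numeric vector of peak locations (molecules); may be empty.
#' @export
find_kde_peaks <- function(dist, prominence_frac = 0.05) {
  stopifnot(inherits(dist, "stoichiometry_distribution"))
  idx <- find_peaks_prominence(dist$kde_grid, dist$kde_density,
                               prominence_frac)
  dist$kde_grid[idx]
}

#' Oligomer periodicity from weighted inter-peak intervals
#'
#' Aggregates the intervals between consecutive sorted stoichiometry-KDE
#' peaks across acquisitions, weights each interval `d` by `1 / sqrt(d)`
#' (discounting the larger shot noise of broader intervals), and builds a
#' weighted Gaussian KDE of the intervals with bandwidth
#' `kernel_width * sqrt(mean_stoich / n_intervals)` (widening with the shot
#' noise of peaks at higher stoichiometry, narrowing with the number of
#' intervals). The periodicity is the mode of that distribution; its 95% CI
#' is the percentile interval of the mode over nonparametric bootstrap
#' resamples of the interval set.
#'
#' @param peaks_per_acquisition List of numeric peak-location vectors, one
#'   per acquisition (a single numeric vector is treated as one
#'   acquisition).
#' @param mean_stoich Mean of the per-track stoichiometries in the
#'   aggregated population.
#' @param kernel_width Base kernel width in molecules (default 0.7).
#' @param n_boot Bootstrap replicates for the CI (default 1000).
#' @param all_pairs If `TRUE`, use all pairwise peak differences within an
#'   acquisition instead of consecutive spacings.
#' @param prominence_frac Unused here; reserved for pipeline symmetry.
#' @return An object of class `periodicity_result`: list with `intervals`
#'   (data frame `interval`, `weight`), `kde2_width`, `mode`, `ci95`,
#'   `n_intervals`, `kde_grid`, `kde_density`.
#' @examples
#' periodicity(list(c(5, 10, 15)), mean_stoich = 7.5, n_boot = 100)$mode
#' @export
periodicity <- function(peaks_per_acquisition, mean_stoich,
                        kernel_width = 0.7, n_boot = 1000,
                        all_pairs = FALSE, prominence_frac = 0.05) {
  if (is.numeric(peaks_per_acquisition))
    peaks_per_acquisition <- list(peaks_per_acquisition)
  stopifnot(is.list(peaks_per_acquisition), mean_stoich > 0,
            kernel_width > 0, n_boot >= 1)
  intervals <- unlist(lapply(peaks_per_acquisition, function(p) {
    p <- sort(p)
    if (length(p) < 2) return(numeric(0))
    if (all_pairs) as.numeric(stats::dist(p)) else diff(p)
  }))
  if (length(intervals) == 0)
    stop("periodicity needs at least one acquisition with >= 2 peaks")
  stopifnot(all(intervals > 0))
  w <- 1 / sqrt(intervals)
  n_int <- length(intervals)
  bw <- kernel_width * sqrt(mean_stoich / n_int)
  grid <- seq(0, max(intervals) + 3 * bw, by = bw / 20)
  dens <- wkde_density(intervals, bw, grid, weights = w)
  mode <- grid[which.max(dens)]
  boot_modes <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n_int, n_int, replace = TRUE)
    wkde_mode(intervals[idx], bw, grid, weights = w[idx])
  }, numeric(1))
  ci95 <- quantile(boot_modes, c(0.025, 0.975), names = FALSE)
  structure(
    list(intervals = data.frame(interval = intervals, weight = w),
         kde2_width = bw, mode = mode,
         ci95 = c(lo = ci95[1], hi = ci95[2]),
         n_intervals = n_int, kde_grid = grid, kde_density = dens),
    class = "periodicity_result"
  )
}

#' @export
print.periodicity_result <- function(x, ...) {
  cat(sprintf(
    "Periodicity: mode %.2f molecules (95%% CI %.2f-%.2f, n = %d intervals)\n",
    x$mode, x$ci95[["lo"]], x$ci95[["hi"]], x$n_intervals))
  invisible(x)
}

#' @export
plot.periodicity_result <- function(x, ...) {
  plot(x$kde_grid, x$kde_density, type = "l",
       xlab = "inter-peak interval (molecules)",
       ylab = "weighted density", ...)
  abline(v = x$mode, lty = 3, col = "grey40")
  invisible(x)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Full molecular counting pipeline
#'
#' Runs, in order: terminal-step brightness calibration, per-track 4-frame
#' backward extrapolation and normalization by the calibrated brightness,
#' the fixed-bandwidth stoichiometry KDE with peak finding (per acquisition
#' and pooled), and the weighted inter-peak interval periodicity analysis.
#' Tracks shorter than `min_track_length` frames or first detected after
#' `start_frame_limit` are excluded from counting. When no acquisition
#' yields two or more peaks the periodicity is `NULL` and the reason is
#' recorded in `notes`.
#'
#' @param x Either a data frame with columns `track_id`, `frame`,
#'   `intensity` (or `intensity_pe`), optionally `acquisition`; or a list
#'   of numeric trace vectors (one acquisition).
#' @param kernel_width Stoichiometry KDE kernel SD, molecules.
#' @param prominence_frac Peak prominence threshold (fraction of max
#'   density).
#' @param start_frame_limit Latest allowed first-detection frame.
#' @param min_track_length Minimum detections per track.
#' @param n_frames Acquisition length; inferred when `NULL`.
#' @param n_boot Bootstrap replicates for the periodicity CI.
#' @param min_steps Minimum terminal calibration steps.
#' @param all_pairs Use all pairwise peak intervals (default consecutive).
#' @return An object of class `counting_report`: list with `calibration`,
#'   `stoichiometries` (data frame `acquisition`, `track_id`,
#'   `stoichiometry`), `distribution` (pooled), `peaks` (pooled),
#'   `peaks_per_acquisition`, `periodicity` (or `NULL`), `n_tracks`,
#'   `n_intervals`, `notes`.
#' @export
run_counting_pipeline <- function(x, kernel_width = 0.7,
                                  prominence_frac = 0.05,
                                  start_frame_limit = 4,
                                  min_track_length = 4, n_frames = NULL,
                                  n_boot = 1000, min_steps = 20,
                                  all_pairs = FALSE) {
  tab <- with_stage("input", as_track_table(x))
  if (nrow(tab) == 0) stop("[input] empty input: no detections")
  if (is.null(n_frames)) n_frames <- max(tab$frame) + 1L
  cal <- with_stage("calibration",
                    calibrate_brightness(tab, n_frames = n_frames,
                                         min_steps = min_steps))
  key <- interaction(tab$acquisition, tab$track_id, drop = TRUE)
  stoich_rows <- with_stage("stoichiometry", {
    pieces <- lapply(split(tab, key), function(tr) {
      if (nrow(tr) < min_track_length) return(NULL)
      if (min(tr$frame) > start_frame_limit) return(NULL)
      data.frame(acquisition = tr$acquisition[1], track_id = tr$track_id[1],
                 stoichiometry = stoichiometry(tr, cal, start_frame_limit))
    })
    out <- do.call(rbind, pieces)
    if (is.null(out) || nrow(out) == 0)
      stop("no tracks usable for counting (length >= ", min_track_length,
           ", start <= frame ", start_frame_limit, ")")
    rownames(out) <- NULL
    out
  })
  dist_all <- with_stage("kde",
                         stoichiometry_kde(stoich_rows$stoichiometry,
                                           kernel_width))
  peaks_all <- find_kde_peaks(dist_all, prominence_frac)
  peaks_acq <- with_stage("kde", lapply(
    split(stoich_rows$stoichiometry, stoich_rows$acquisition),
    function(s) find_kde_peaks(stoichiometry_kde(s, kernel_width),
                               prominence_frac)))
  notes <- character(0)
  per <- NULL
  if (any(vapply(peaks_acq, length, 1L) >= 2)) {
    per <- with_stage("periodicity",
                      periodicity(peaks_acq,
                                  mean_stoich = mean(stoich_rows$stoichiometry),
                                  kernel_width = kernel_width,
                                  n_boot = n_boot, all_pairs = all_pairs))
  } else {
    notes <- c(notes,
               "periodicity skipped: no acquisition produced >= 2 KDE peaks")
  }
  structure(
    list(calibration = cal, stoichiometries = stoich_rows,
         distribution = dist_all, peaks = peaks_all,
         peaks_per_acquisition = peaks_acq, periodicity = per,
         n_tracks = nrow(stoich_rows),
         n_intervals = if (is.null(per)) 0L else per$n_intervals,
         notes = notes),
    class = "counting_report"
  )
}

#' @export
print.counting_report <- function(x, ...) {
  cat("Slimfield molecular counting report\n")
  print(x$calibration)
  cat(sprintf("  %d tracks counted; pooled KDE peaks at: %s\n", x$n_tracks,
              paste(signif(x$peaks, 4), collapse = ", ")))
  if (!is.null(x$periodicity)) print(x$periodicity)
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
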