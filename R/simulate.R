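# Photobleaching trace and image-stack simulator.
#
# The generative model is deliberately minimal: constant emission per
# fluorophore until a memoryless bleach event, additive Gaussian noise on the
# per-frame summed intensity, and (for image rendering) a symmetric 2-D
# Gaussian point-spread function whose integrated intensity equals the trace
# value. Everything downstream (detection, calibration, counting) is
# validated against the ground truth this module records.

# Draw geometric fluorophore lifetimes. A fluorophore with lifetime L emits
# in frames 0..L (0-based) so the survival probability at frame f is
# (1 - bleach_prob)^f and frame 0 is always emitted.
sim_lifetimes <- function(n, bleach_prob) {
  if (n == 0) return(integer(0))
  if (bleach_prob >= 1) return(integer(n))  # bleach after the first frame
  rgeom(n, bleach_prob)
}

# Number of unbleached fluorophores per frame (vector of length n_frames)
# from the lifetime draws.
unbleached_counts <- function(lifetimes, n_frames) {
  n <- length(lifetimes)
  if (n == 0) return(integer(n_frames))
  # bleached_before[f+1] = number of fluorophores with lifetime < f
  last_emit <- pmin(lifetimes, n_frames)  # cap for tabulation only
  counts_by_life <- tabulate(last_emit + 1L, nbins = n_frames)
  n - c(0L, cumsum(counts_by_life)[seq_len(n_frames - 1L)])
}

#' Simulate one photobleaching intensity trace
#'
#' Generates the background-corrected summed intensity of a single
#' diffraction-limited complex carrying `n_fluorophores` tagged subunits.
#' Each fluorophore contributes `params$brightness_pe` photoelectrons per
#' frame until its (geometric-lifetime) bleach event; additive Gaussian
#' noise of SD `params$noise_sd_pe` is applied per frame.
#'
#' @param params A [simulation_params()] object.
#' @param config An [acquisition_config()] object.
#' @param n_fluorophores Number of emitting fluorophores at frame 0.
#' @param return_truth If `TRUE`, return a list with the trace, the
#'   per-frame unbleached counts and the per-fluorophore bleach frames
#'   (first dark frame, 0-based).
#'
#' @return Numeric vector of per-frame intensities (photoelectrons), frames
#'   0-based; or a list when `return_truth = TRUE`.
#' @examples
#' p <- simulation_params(noise_sd_pe = 0)
#' tr <- simulate_trace(p, acquisition_config(), n_fluorophores = 5)
#' tr[1]  # 5 x 56 = 280 photoelectrons before any bleaching
#' @export
simulate_trace <- function(params, config, n_fluorophores,
                           return_truth = FALSE) {
  stopifnot(inherits(params, "simulation_params"),
            inherits(config, "acquisition_config"),
            is.numeric(n_fluorophores), length(n_fluorophores) == 1,
            is.finite(n_fluorophores), n_fluorophores >= 0,
            n_fluorophores == round(n_fluorophores))
  nf <- config$n_frames
  lifetimes <- sim_lifetimes(as.integer(n_fluorophores), params$bleach_prob)
  counts <- unbleached_counts(lifetimes, nf)
  trace <- params$brightness_pe * counts
  if (params$noise_sd_pe > 0)
    trace <- trace + rnorm(nf, 0, params$noise_sd_pe)
  if (!return_truth) return(trace)
  list(trace = trace, counts = counts, bleach_frame = lifetimes + 1L)
}

#' Simulate a population of oligomeric complexes with ground truth
#'
#' Draws, for each complex, a true subunit count equal to
#' `unit_stoichiometry * m` with the multiple `m` sampled from
#' `multiple_weights`, a tagged-fluorophore count from
#' `Binomial(subunits, detection_fraction)`, and a photobleaching trace via
#' [simulate_trace()]. When `params$seed` is set the whole population is
#' bit-reproducible.
#'
#' @param params A [simulation_params()] object.
#' @param config An [acquisition_config()] object.
#'
#' @return An object of class `slim_population`: a list with `traces` (list
#'   of numeric vectors), `truth` (data frame with `complex_id`, `subunits`,
#'   `tagged`), `bleach_frames` (list of integer vectors, first dark frame
#'   per fluorophore), and the `params`/`config` used.
#' @examples
#' pop <- simulate_population(simulation_params(n_complexes = 20, seed = 1),
#'                            acquisition_config())
#' table(pop$truth$subunits)
#' @export
simulate_population <- function(params, config = acquisition_config()) {
  stopifnot(inherits(params, "simulation_params"),
            inherits(config, "acquisition_config"))
  if (length(params$multiple_weights) == 0)
    stop("multiple_weights is empty")
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_complexes
  mult <- sample.int(length(params$multiple_weights), n, replace = TRUE,
                     prob = params$multiple_weights)
  subunits <- params$unit_stoichiometry * mult
  tagged <- rbinom(n, subunits, params$detection_fraction)
  traces <- vector("list", n)
  bleach <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_trace(params, config, tagged[i], return_truth = TRUE)
    traces[[i]] <- sim$trace
    bleach[[i]] <- sim$bleach_frame
  }
  structure(
    list(traces = traces,
         truth = data.frame(complex_id = seq_len(n), subunits = subunits,
                            tagged = tagged),
         bleach_frames = bleach,
         params = params, config = config),
    class = "slim_population"
  )
}

#' @export
print.slim_population <- function(x, ...) {
  cat("Simulated Slimfield population:", nrow(x$truth), "complexes,",
      x$config$n_frames, "frames\n")
  cat("  unit stoichiometry:", x$params$unit_stoichiometry,
      "| tagged counts:", paste(range(x$truth$tagged), collapse = "-"), "\n")
  invisible(x)
}

# Integrated Gaussian mass of a PSF centred at `centre` (pixel units,
# 1-based pixel-centre convention) over pixels `idx`, using the error
# function over pixel edges so the total over the image equals 1.
pixel_mass <- function(idx, centre, sigma) {
  stats::pnorm(idx + 0.5, centre, sigma) - stats::pnorm(idx - 0.5, centre, sigma)
}

#' Render a simulated population into an image stack
#'
#' Places each complex at a fixed (or slowly diffusing) position and renders
#' its per-frame trace value as a symmetric 2-D Gaussian spot of that
#' integrated intensity on a uniform background, mimicking a
#' diffraction-limited fluorescence image sequence. Spot positions are drawn
#' uniformly at least 9 px from the frame border (so the photometry annulus
#' always fits) and, when given, inside `roi_mask`.
#'
#' @param population A `slim_population` from [simulate_population()].
#' @param config An [acquisition_config()]; its `image_shape` sets the frame
#'   size.
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels.
#' @param background_pe Uniform background level, photoelectrons per pixel.
#' @param roi_mask Optional logical matrix of `image_shape`; spots are placed
#'   only where `TRUE`.
#' @param positions Optional data frame `spot_id, row, col` of fixed spot
#'   positions (1-based pixel units) overriding random placement.
#' @param diffusion_sd_px Per-frame random-walk SD in pixels (0 = static).
#' @param min_separation_px Minimum distance between randomly placed spots.
#' @param noise_sd_px Optional per-pixel additive Gaussian noise SD
#'   (photoelectrons); trace-level noise is already in the traces.
#'
#' @return A list with `stack` (array rows x cols x frames, photoelectrons),
#'   `centroids` (data frame `spot_id, frame, row, col`, frames 0-based),
#'   `background_pe` and `psf_sigma_px`.
#' @export
render_image_stack <- function(population, config = population$config,
                               psf_sigma_px = 1.3, background_pe = 10,
                               roi_mask = NULL, positions = NULL,
                               diffusion_sd_px = 0, min_separation_px = 12,
                               noise_sd_px = 0) {
  stopifnot(inherits(population, "slim_population"), psf_sigma_px > 0,
            background_pe >= 0)
  shape <- config$image_shape
  nr <- shape[1]; nc <- shape[2]
  nf <- config$n_frames
  n_spots <- length(population$traces)
  margin <- 9
  if (nr < 2 * margin + 1 || nc < 2 * margin + 1)
    stop("image_shape too small for the photometry margin (need > 19 px)")

  if (is.null(positions)) {
    ok_px <- matrix(FALSE, nr, nc)
    ok_px[(margin + 1):(nr - margin), (margin + 1):(nc - margin)] <- TRUE
    if (!is.null(roi_mask)) {
      stopifnot(is.logical(roi_mask), all(dim(roi_mask) == shape))
      if (!any(roi_mask)) stop("roi_mask is empty")
      ok_px <- ok_px & roi_mask
    }
    cand <- which(ok_px, arr.ind = TRUE)
    if (nrow(cand) == 0) stop("no admissible spot positions inside the mask")
    rows <- numeric(0); cols <- numeric(0)
    for (i in seq_len(n_spots)) {
      placed <- FALSE
      for (attempt in seq_len(500)) {
        j <- cand[sample.int(nrow(cand), 1), ]
        pr <- j[1] + runif(1, -0.5, 0.5)
        pc <- j[2] + runif(1, -0.5, 0.5)
        if (length(rows) == 0 ||
            all(sqrt((rows - pr)^2 + (cols - pc)^2) >= min_separation_px)) {
          rows <- c(rows, pr); cols <- c(cols, pc); placed <- TRUE; break
        }
      }
      if (!placed)
        stop("could not place ", n_spots, " spots at min separation ",
             min_separation_px, " px; enlarge image_shape or the mask")
    }
    positions <- data.frame(spot_id = seq_len(n_spots), row = rows, col = cols)
  } else {
    stopifnot(all(c("spot_id", "row", "col") %in% names(positions)),
              nrow(positions) == n_spots)
    if (any(positions$row < 1 | positions$row > nr |
            positions$col < 1 | positions$col > nc))
      stop("spot placed outside image bounds")
  }

  stack <- array(background_pe, dim = c(nr, nc, nf))
  cent <- vector("list", nf)
  half <- ceiling(4 * psf_sigma_px)
  pr <- positions$row; pc <- positions$col
  for (f in seq_len(nf)) {
    if (diffusion_sd_px > 0 && f > 1) {
      pr <- pmin(pmax(pr + rnorm(n_spots, 0, diffusion_sd_px), margin + 1),
                 nr - margin)
      pc <- pmin(pmax(pc + rnorm(n_spots, 0, diffusion_sd_px), margin + 1),
                 nc - margin)
    }
    for (s in seq_len(n_spots)) {
      v <- max(population$traces[[s]][f], 0)
      if (v == 0) next
      r0 <- max(1, floor(pr[s]) - half); r1 <- min(nr, ceiling(pr[s]) + half)
      c0 <- max(1, floor(pc[s]) - half); c1 <- min(nc, ceiling(pc[s]) + half)
      mr <- pixel_mass(r0:r1, pr[s], psf_sigma_px)
      mc <- pixel_mass(c0:c1, pc[s], psf_sigma_px)
      stack[r0:r1, c0:c1, f] <- stack[r0:r1, c0:c1, f] + v * outer(mr, mc)
    }
    cent[[f]] <- data.frame(spot_id = seq_len(n_spots), frame = f - 1L,
                            row = pr, col = pc)
  }
  if (noise_sd_px > 0)
    stack <- stack + array(rnorm(length(stack), 0, noise_sd_px), dim = dim(stack))
  list(stack = stack, centroids = do.call(rbind, cent),
       background_pe = background_pe, psf_sigma_px = psf_sigma_px)
}

#' Write / read an image stack as multi-page 16-bit TIFF
#'
#' Photoelectron values are linearly quantized to 16-bit camera counts on
#' export; the photoelectrons-per-count scale is recorded in a JSON sidecar
#' (`<path>.json`) and reapplied on reading, so a write/read round trip
#' returns photoelectrons to within quantization error.
#'
#' @param stack Numeric array `rows x cols x frames` (photoelectrons).
#' @param path Output TIFF path.
#' @param pe_per_count Photoelectrons per camera count; defaults to spanning
#'   the stack's dynamic range over 16 bits.
#' @return `write_stack_tiff()` returns `path` invisibly; `read_stack_tiff()`
#'   returns the stack array in photoelectrons.
#' @export
write_stack_tiff <- function(stack, path, pe_per_count = NULL) {
  stopifnot(is.array(stack), length(dim(stack)) == 3, all(is.finite(stack)))
  if (is.null(pe_per_count)) {
    mx <- max(stack, 1e-12)
    pe_per_count <- mx / 65000
  }
  counts <- pmin(pmax(round(stack / pe_per_count), 0), 65535)
  pages <- lapply(seq_len(dim(stack)[3]), function(f) counts[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(pe_per_count = pe_per_count, dim = dim(stack), bits = 16L),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) stack[, , f] <- pages[[f]]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    stack <- stack * meta$pe_per_count
  }
  stack
}
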