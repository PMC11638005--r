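#' Acquisition settings for a Slimfield image sequence
#'
#' Frame timing and camera geometry of one acquisition. The defaults
#' reproduce a typical Slimfield photobleaching protocol: 10 ms exposure per
#' frame at 180 frames/s for about 5 s (900 frames), sampled at 53 nm/pixel,
#' which is long enough to follow a fluorescent-protein spot from its initial
#' unbleached state down to terminal single-molecule blinking.
#'
#' @param exposure_s Exposure time per frame in seconds.
#' @param frame_rate_hz Acquisition rate in frames per second.
#' @param n_frames Number of frames in the sequence (at least 8).
#' @param pixel_nm Pixel size at the sample plane, nanometres per pixel.
#' @param image_shape Integer vector `c(rows, cols)` of the frame size in
#'   pixels.
#'
#' @return An object of class `acquisition_config`.
#' @examples
#' cfg <- acquisition_config()
#' cfg$n_frames * cfg$exposure_s  # ~5 s of photobleaching
#' @export
acquisition_config <- function(exposure_s = 0.010, frame_rate_hz = 180,
                               n_frames = 900, pixel_nm = 53,
                               image_shape = c(64L, 64L)) {
  stopifnot(
    is.numeric(exposure_s), length(exposure_s) == 1, is.finite(exposure_s),
    exposure_s > 0,
    is.numeric(frame_rate_hz), length(frame_rate_hz) == 1,
    is.finite(frame_rate_hz), frame_rate_hz > 0,
    is.numeric(n_frames), length(n_frames) == 1, is.finite(n_frames),
    n_frames >= 8, n_frames == round(n_frames),
    is.numeric(pixel_nm), length(pixel_nm) == 1, pixel_nm > 0,
    is.numeric(image_shape), length(image_shape) == 2, all(image_shape >= 1)
  )
  structure(
    list(exposure_s = exposure_s, frame_rate_hz = frame_rate_hz,
         n_frames = as.integer(n_frames), pixel_nm = pixel_nm,
         image_shape = as.integer(image_shape)),
    class = "acquisition_config"
  )
}

#' Ground-truth parameters for a simulated complex population
#'
#' Parameters of the generative model used throughout the test suite: each
#' complex carries an integer number of subunits equal to the fundamental
#' oligomeric unit times a small integer multiple, each subunit carries a
#' matured fluorescent tag with probability `detection_fraction`, each
#' fluorophore emits a constant `brightness_pe` photoelectrons per frame
#' until it bleaches (memoryless, geometric lifetime), and the per-frame
#' summed intensity carries additive Gaussian camera noise.
#'
#' Defaults emulate a pentameric bestrophin-like channel population imaged at
#' single-molecule sensitivity: 56 photoelectrons/frame/molecule with a 9
#' photoelectron noise spread, pentamer unit with higher multiples of the
#' unit at decreasing frequency, and a mean fluorophore lifetime of 250
#' frames (about 1.4 s at 180 frames/s) so bleaching completes well within a
#' 5 s acquisition.
#'
#' @param unit_stoichiometry Integer subunits in the fundamental oligomer.
#' @param multiple_weights Probability vector over successive integer
#'   multiples of the unit (first element = 1x the unit). Must sum to 1.
#' @param brightness_pe Photoelectrons per frame emitted by one fluorophore.
#' @param bleach_prob Per-fluorophore, per-frame bleaching probability in
#'   (0, 1].
#' @param detection_fraction Probability a subunit carries a fluorescent,
#'   matured tag, in \[0, 1\].
#' @param noise_sd_pe Additive Gaussian noise SD on each frame's summed
#'   intensity, photoelectrons.
#' @param n_complexes Number of complexes (tracks) to simulate.
#' @param seed Optional RNG seed; when set, simulation output is
#'   bit-reproducible.
#'
#' @return An object of class `simulation_params`.
#' @examples
#' simulation_params(n_complexes = 50, seed = 1)
#' @export
simulation_params <- function(unit_stoichiometry = 5,
                              multiple_weights = c(0.6, 0.25, 0.1, 0.05),
                              brightness_pe = 56,
                              bleach_prob = 0.004,
                              detection_fraction = 1.0,
                              noise_sd_pe = 9,
                              n_complexes = 347,
                              seed = NULL) {
  stopifnot(
    is.numeric(unit_stoichiometry), length(unit_stoichiometry) == 1,
    unit_stoichiometry >= 1, unit_stoichiometry == round(unit_stoichiometry),
    is.numeric(multiple_weights), length(multiple_weights) >= 1,
    all(is.finite(multiple_weights)), all(multiple_weights >= 0),
    is.numeric(brightness_pe), length(brightness_pe) == 1,
    is.finite(brightness_pe), brightness_pe > 0,
    is.numeric(bleach_prob), length(bleach_prob) == 1, is.finite(bleach_prob),
    bleach_prob > 0, bleach_prob <= 1,
    is.numeric(detection_fraction), length(detection_fraction) == 1,
    detection_fraction >= 0, detection_fraction <= 1,
    is.numeric(noise_sd_pe), length(noise_sd_pe) == 1, is.finite(noise_sd_pe),
    noise_sd_pe >= 0,
    is.numeric(n_complexes), length(n_complexes) == 1, n_complexes >= 1,
    n_complexes == round(n_complexes)
  )
  if (abs(sum(multiple_weights) - 1) > 1e-8)
    stop("multiple_weights must sum to 1")
  if (!is.null(seed))
    stopifnot(is.numeric(seed), length(seed) == 1, seed == round(seed))
  structure(
    list(unit_stoichiometry = as.integer(unit_stoichiometry),
         multiple_weights = multiple_weights,
         brightness_pe = brightness_pe,
         bleach_prob = bleach_prob,
         detection_fraction = detection_fraction,
         noise_sd_pe = noise_sd_pe,
         n_complexes = as.integer(n_complexes),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "simulation_params"
  )
}
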