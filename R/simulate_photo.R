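# Synthetic photophysiology records: PAM saturating-pulse fluorometry and
# electrochromic-shift (ECS) absorbance traces with known ground truth.

#' Simulate a PAM saturating-pulse record
#'
#' Builds a pulse-by-pulse fluorometry record from a prescribed NPQ
#' trajectory: at each saturating pulse the maximal yield is
#' `Fm' = Fm / (1 + NPQ)` (so NPQ recomputed from the record returns the
#' injected trajectory exactly, up to noise) and the stationary fluorescence
#' is `F = Fm' * (1 - Y(II))` for the prescribed operating yield.
#'
#' @param pulse_times_s Times of the saturating pulses, seconds, increasing.
#' @param phase Character vector, `"dark"` or `"light"`, one per pulse.
#' @param npq_values Prescribed NPQ at each pulse (>= 0).
#' @param yii_values Prescribed PSII operating yield Y(II) at each pulse, in
#'   \[0, 1); default 0.5 throughout.
#' @param fm Dark-adapted maximal fluorescence yield (arbitrary units).
#' @param fo Dark-adapted minimal fluorescence yield.
#' @param noise_sd Additive Gaussian noise SD applied to `F` and `Fm'`.
#'
#' @return A `pulse_record` data frame with columns `time_s`, `F`,
#'   `Fm_prime`, `phase`, and the injected `npq_true`.
#' @examples
#' rec <- simulate_pam_trace(1:5, rep("light", 5), npq_values = rep(0, 5))
#' all(rec$Fm_prime == 1)  # NPQ = 0 leaves Fm' at Fm
#' @export
simulate_pam_trace <- function(pulse_times_s, phase, npq_values,
                               yii_values = NULL, fm = 1.0, fo = 0.2,
                               noise_sd = 0) {
  n <- length(pulse_times_s)
  stopifnot(n >= 1, length(phase) == n, length(npq_values) == n,
            all(phase %in% c("dark", "light")), all(npq_values >= 0),
            fm > 0, fo > 0, fo < fm, noise_sd >= 0,
            !is.unsorted(pulse_times_s))
  if (is.null(yii_values)) yii_values <- rep(0.5, n)
  stopifnot(length(yii_values) == n, all(yii_values >= 0), all(yii_values < 1))
  fm_prime <- fm / (1 + npq_values)
  f_stat <- fm_prime * (1 - yii_values)
  if (noise_sd > 0) {
    fm_prime <- fm_prime + rnorm(n, 0, noise_sd)
    f_stat <- pmin(f_stat + rnorm(n, 0, noise_sd), fm_prime * 0.999)
  }
  rec <- data.frame(time_s = pulse_times_s, F = f_stat, Fm_prime = fm_prime,
                    phase = phase, npq_true = npq_values)
  attr(rec, "fm") <- fm
  attr(rec, "fo") <- fo
  class(rec) <- c("pulse_record", "data.frame")
  rec
}

#' Simulate an electrochromic-shift (ECS) absorbance trace
#'
#' Square-wave light response: the ECS signal (A520 - A545) sits at a light
#' plateau, then after light-off decays single-exponentially with time
#' constant `tau_true` towards a floor `pmf_true` below the plateau. An
#' optional slow recovery towards a dark steady state above the floor
#' emulates the membrane-potential (delta-psi) component used for
#' PMF partitioning: the steady state sits `dpsi_frac * pmf_true` above the
#' post-illumination minimum. The slow component is delayed by five fast
#' time constants so the fast decay (which carries tau and the trough) and
#' the recovery are kinetically separated, as they must be for the
#' steady-state partitioning convention to be well defined.
#'
#' @param pmf_true Amplitude of the light-minus-minimum ECS drop (the true
#'   PMF in the trace's units; normalized units if you also pass `ecs_st`).
#' @param tau_true Decay time constant, seconds.
#' @param noise_sd Additive Gaussian noise SD on each absorbance channel.
#' @param dpsi_frac Fraction of `pmf_true` recovered at the dark steady
#'   state (0 = pure decay to the floor).
#' @param tau_slow Time constant of the slow recovery, seconds.
#' @param light_duration_s,dark_duration_s Length of the light and dark
#'   segments, seconds.
#' @param dt Sampling interval, seconds.
#' @param ecs_st Optional single-turnover normalization amplitude stored on
#'   the trace.
#'
#' @return An object of class `ecs_trace`: list with `time_s`, `a520`,
#'   `a545`, `light_off_time_s`, `ecs_st`, and the injected truth
#'   (`pmf_true`, `tau_true`, `dpsi_frac`).
#' @examples
#' tr <- simulate_ecs_trace(pmf_true = 1, tau_true = 0.1)
#' g_h(tr)  # 1 / 0.1 = 10 s^-1
#' @export
simulate_ecs_trace <- function(pmf_true, tau_true, noise_sd = 0,
                               dpsi_frac = 0, tau_slow = 1.0,
                               light_duration_s = 1, dark_duration_s = 2,
                               dt = 0.001, ecs_st = NULL) {
  stopifnot(pmf_true > 0, tau_true > 0, noise_sd >= 0,
            dpsi_frac >= 0, dpsi_frac < 1, tau_slow > tau_true,
            light_duration_s > 0, dark_duration_s >= 0.2, dt > 0)
  t <- seq(0, light_duration_s + dark_duration_s, by = dt)
  t_off <- light_duration_s
  plateau <- pmf_true          # light plateau, floor at 0
  ecs <- ifelse(t < t_off, plateau, NA_real_)
  dtk <- t[t >= t_off] - t_off
  delay <- 5 * tau_true
  ecs[t >= t_off] <- plateau * exp(-dtk / tau_true) +
    dpsi_frac * pmf_true * (1 - exp(-pmax(dtk - delay, 0) / tau_slow))
  a545 <- numeric(length(t))
  a520 <- ecs
  if (noise_sd > 0) {
    a520 <- a520 + rnorm(length(t), 0, noise_sd)
    a545 <- a545 + rnorm(length(t), 0, noise_sd)
  }
  structure(
    list(time_s = t, a520 = a520, a545 = a545, light_off_time_s = t_off,
         ecs_st = ecs_st, pmf_true = pmf_true, tau_true = tau_true,
         dpsi_frac = dpsi_frac),
    class = "ecs_trace"
  )
}
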