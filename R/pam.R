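# Chlorophyll-fluorescence (PAM) parameters. All functions are pure and
# vectorized over their arguments.

check_pos <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(name, " must be positive and finite")
  invisible(x)
}

#' Non-photochemical quenching
#'
#' `NPQ = (Fm - Fm') / Fm'`, the Stern-Volmer measure of regulated heat
#' dissipation, from the dark-adapted and light-adapted maximal
#' fluorescence yields.
#'
#' @param fm Dark-adapted maximal fluorescence yield.
#' @param fm_prime Light-adapted maximal yield at a saturating pulse.
#' @return NPQ (dimensionless).
#' @examples
#' npq(1.0, 0.5)  # 1
#' @export
npq <- function(fm, fm_prime) {
  check_pos(fm_prime, "fm_prime")
  (fm - fm_prime) / fm_prime
}

#' PSII operating quantum yield
#'
#' `Y(II) = (Fm' - F) / Fm'`: the fraction of absorbed excitation used for
#' PSII photochemistry in the light.
#'
#' @param fm_prime Light-adapted maximal yield.
#' @param f Stationary fluorescence yield.
#' @return Y(II) (dimensionless).
#' @export
yield_ii <- function(fm_prime, f) {
  check_pos(fm_prime, "fm_prime")
  (fm_prime - f) / fm_prime
}

#' Maximal PSII quantum efficiency
#'
#' `Fv/Fm = (Fm - Fo) / Fm` from the dark-adapted minimal and maximal
#' yields.
#'
#' @param fo Dark-adapted minimal fluorescence yield.
#' @param fm Dark-adapted maximal fluorescence yield.
#' @return Fv/Fm (dimensionless).
#' @export
fv_over_fm <- function(fo, fm) {
  check_pos(fm, "fm")
  (fm - fo) / fm
}

#' Estimated minimal fluorescence in the light
#'
#' The Oxborough-Baker estimate `Fo' = Fo / (Fv/Fm + Fo/Fm')`, used when
#' Fo' is not measured directly after far-red re-oxidation.
#'
#' @param fo Dark-adapted minimal yield.
#' @param fv_fm Dark-adapted Fv/Fm.
#' @param fm_prime Light-adapted maximal yield.
#' @return Fo' in fluorescence units.
#' @examples
#' fo_prime(0.2, 0.8, 0.8)  # 0.2 / (0.8 + 0.25) = 0.19047...
#' @export
fo_prime <- function(fo, fv_fm, fm_prime) {
  check_pos(fo, "fo"); check_pos(fm_prime, "fm_prime")
  denom <- fv_fm + fo / fm_prime
  check_pos(denom, "fv_fm + fo/fm_prime")
  fo / denom
}

#' Fraction of open PSII centres (qL)
#'
#' `qL = (Fm' - F) * Fo' / ((Fm' - Fo') * F)` in the lake-model
#' parameterization; `1 - qL` indexes the reduction state of the
#' plastoquinone pool.
#'
#' @param f Stationary fluorescence yield.
#' @param fm_prime Light-adapted maximal yield.
#' @param fo_prime Minimal yield in the light (measured or from
#'   [fo_prime()]).
#' @return A list with `qL` and `one_minus_qL`.
#' @export
q_l <- function(f, fm_prime, fo_prime) {
  check_pos(f, "f"); check_pos(fm_prime, "fm_prime")
  check_pos(fo_prime, "fo_prime")
  if (any(fm_prime <= fo_prime))
    stop("degenerate inputs: fm_prime must exceed fo_prime")
  ql <- (fm_prime - f) * fo_prime / ((fm_prime - fo_prime) * f)
  list(qL = ql, one_minus_qL = 1 - ql)
}

#' Fast-relaxing NPQ at a light-to-dark transition
#'
#' NPQ at the last light point minus the minimum NPQ over the subsequent
#' dark points: the rapidly reversible (qE-like, lumen-pH dependent)
#' component of quenching.
#'
#' @param npq_series Data frame with columns `npq` and `phase`
#'   (`"dark"`/`"light"`), ordered in time.
#' @return Fast-relaxing NPQ (dimensionless).
#' @examples
#' s <- data.frame(npq = c(1.0, 1.2, 0.6, 0.4),
#'                 phase = c("light", "light", "dark", "dark"))
#' fast_relaxing_npq(s)  # 1.2 - 0.4 = 0.8
#' @export
fast_relaxing_npq <- function(npq_series) {
  stopifnot(all(c("npq", "phase") %in% names(npq_series)),
            all(npq_series$phase %in% c("dark", "light")))
  light_idx <- which(npq_series$phase == "light")
  if (length(light_idx) == 0)
    stop("series has no light phase")
  last_light <- max(light_idx)
  dark_after <- which(npq_series$phase == "dark" &
                      seq_len(nrow(npq_series)) > last_light)
  if (length(dark_after) == 0)
    stop("series has no dark phase after the light-to-dark transition")
  npq_series$npq[last_light] - min(npq_series$npq[dark_after])
}
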