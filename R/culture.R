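# Culture-level quantities: specific growth rate and total chlorophyll.

#' Specific growth rate of a culture
#'
#' `mu = ln(N2 / N1) / t` from two cell-density measurements `t` hours
#' apart.
#'
#' @param n1,n2 Cell densities (cells/mL) at the start and end of the
#'   interval.
#' @param t Interval length in hours.
#' @return Growth rate in h^-1.
#' @examples
#' specific_growth_rate(1e5, 2e5, 24)  # ln(2)/24 = 0.0289 h^-1
#' @export
specific_growth_rate <- function(n1, n2, t) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop("cell densities must be positive")
  if (any(t <= 0)) stop("time interval must be positive")
  log(n2 / n1) / t
}

#' Total chlorophyll from methanol-extract absorbances
#'
#' `chlorophyll (ug/mL) = 22.12 x A652 + 2.71 x A665` for a methanol
#' extract read at 652 and 665 nm.
#'
#' @param a652,a665 Absorbances at 652 and 665 nm (>= 0).
#' @return Total chlorophyll in micrograms per millilitre.
#' @export
total_chlorophyll <- function(a652, a665) {
  if (any(a652 < 0) || any(a665 < 0)) stop("absorbances must be >= 0")
  22.12 * a652 + 2.71 * a665
}
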