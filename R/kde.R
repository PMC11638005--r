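# Fixed-bandwidth (optionally weighted) Gaussian kernel density estimation
# and peak finding. The counting method prescribes its own bandwidths in
# molecule units, so these helpers take the kernel SD explicitly rather
# than selecting it from the data.

# Evaluate a weighted Gaussian KDE on a grid. Weights need not be
# normalized; the returned density integrates to 1 in the infinite-support
# sense (before any grid truncation).
wkde_density <- function(x, bw, grid, weights = NULL) {
  stopifnot(length(x) >= 1, bw > 0)
  if (is.null(weights)) weights <- rep(1, length(x))
  stopifnot(length(weights) == length(x), all(weights > 0))
  w <- weights / sum(weights)
  as.vector(dnorm(outer(grid, x, "-"), sd = bw) %*% w)
}

wkde_mode <- function(x, bw, grid, weights = NULL) {
  d <- wkde_density(x, bw, grid, weights)
  grid[which.max(d)]
}

# Mode of an (unweighted, bandwidth-selected) KDE; used for brightness
# calibration where no bandwidth is prescribed. Degenerate samples (all
# equal) return the common value exactly.
kde_mode <- function(x, n_grid = 2048) {
  stopifnot(length(x) >= 1)
  if (length(x) == 1 || diff(range(x)) < sqrt(.Machine$double.eps))
    return(x[1])
  d <- density(x, n = n_grid)
  d$x[which.max(d$y)]
}

trapezoid_integral <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Strict-interior local maxima of a density curve with a MATLAB-style
# prominence filter: a peak's prominence is its height minus the higher of
# the two minima separating it from higher ground (or from the grid edge).
find_peaks_prominence <- function(grid, dens, prominence_frac = 0.05) {
  n <- length(dens)
  if (n < 3) return(integer(0))
  is_peak <- which(dens[2:(n - 1)] > dens[1:(n - 2)] &
                   dens[2:(n - 1)] > dens[3:n]) + 1L
  if (length(is_peak) == 0) return(integer(0))
  prom <- vapply(is_peak, function(j) {
    h <- dens[j]
    left <- j - 1
    while (left >= 1 && dens[left] <= h) left <- left - 1
    left_min <- min(dens[max(left, 1):j])
    right <- j + 1
    while (right <= n && dens[right] <= h) right <- right + 1
    right_min <- min(dens[j:min(right, n)])
    h - max(left_min, right_min)
  }, numeric(1))
  is_peak[prom >= prominence_frac * max(dens)]
}
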