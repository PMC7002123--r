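# Brute-force rasterized retina, independent of the analytic arc pipeline.
# The binary field is built directly from the neighbor configuration by
# testing each bin center against every subtended interval; functionals are
# midpoint sums, edges are 0/1 transitions between adjacent bins with the
# unit-weight (Dirac comb) normalization.

raster_field <- function(centers, half_widths, n_bins = 2e5) {
  dphi <- 2 * pi / n_bins
  bins <- -pi + (seq_len(n_bins) - 0.5) * dphi
  V <- logical(n_bins)
  for (k in seq_along(centers)) {
    V <- V | (abs(wrap_angle(bins - centers[k])) <= half_widths[k])
  }
  list(bins = bins, V = V, dphi = dphi)
}

raster_area <- function(rf, kernel) {
  kfun <- if (kernel == "cos") cos else sin
  sum(kfun(rf$bins[rf$V])) * rf$dphi
}

raster_edge_sum <- function(rf, kernel) {
  kfun <- if (kernel == "cos") cos else sin
  n <- length(rf$V)
  trans <- which(rf$V != c(rf$V[n], rf$V[-n]))
  if (!length(trans)) return(0)
  sum(kfun(rf$bins[trans] - rf$dphi / 2))
}

# Random neighbor configurations around a focal agent at the origin.
random_arc_config <- function(n, min_d = 0.6, max_d = 20) {
  d <- runif(n, min_d, max_d)
  ang <- runif(n, -pi, pi)
  list(centers = ang, half_widths = asin(pmin(1, 1 / (2 * d))))
}

# Root of the front-back force balance BL/(2d) = sin(atan(alpha1)):
# independent oracle for the two-agent equilibrium distance.
equilibrium_distance_oracle <- function(alpha1, BL = 1) {
  BL / (2 * sin(atan(alpha1)))
}
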