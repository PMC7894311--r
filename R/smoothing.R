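#' Two-rate smoothing scalar at exact co-limitation
#'
#' When two potentially limiting rates are exactly equal (`x1 = x2 = A`),
#' the smaller root of the smoothing quadratic is `A (1 - sqrt(1 - theta))
#' / theta`, so quadratic smoothing multiplies the co-limited rate by the
#' scalar `(1 - sqrt(1 - theta)) / theta` regardless of the rate's
#' magnitude. At `theta = 1` the scalar is 1 (strict minimum, no
#' reduction); as `theta -> 0` it falls to the rectangular-hyperbola limit
#' of 0.5.
#'
#' @param theta Curvature parameter in `[0, 1]`.
#' @return The dimensionless scalar, with attribute `"reduction_pct"`
#'   (`100 * (1 - scalar)`).
#' @export
two_rate_scalar <- function(theta) {
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]")
  s <- ifelse(theta == 0, 0.5, (1 - sqrt(1 - theta)) / theta)
  attr(s, "reduction_pct") <- 100 * (1 - s)
  s
}

#' Smoothing scalar at triple co-limitation
#'
#' The greatest smoothing-related reduction occurs when all three
#' potentially limiting rates are equal. Because the smoothing quadratics
#' are scale-invariant, the rates can be normalised to 1: the first stage
#' gives `s1 = two_rate_scalar(theta_cj)` and the second stage smooths `s1`
#' against the third (unit) rate with `theta_cjp`.
#'
#' @param theta_cj,theta_cjp Curvature parameters in `(0, 1]`.
#' @return The dimensionless scalar on gross assimilation, with attribute
#'   `"reduction_pct"`.
#' @export
colimitation_scalar <- function(theta_cj, theta_cjp) {
  s1 <- as.numeric(two_rate_scalar(theta_cj))
  s <- smaller_root(theta_cjp, s1, 1)
  attr(s, "reduction_pct") <- 100 * (1 - s)
  s
}

#' Relative reduction surface of quadratic smoothing
#'
#' Percent reduction of gross assimilation under two-stage quadratic
#' smoothing relative to the strict minimum, `100 (min - smoothed) / min`,
#' over a grid of carboxylation- and RuBP-regeneration-limited rates at a
#' fixed TPU-limited rate. The maximum is attained where the rates are
#' equal and the reduction falls monotonically to zero as any one rate
#' grows away from the minimum.
#'
#' @param ac_grid,aj_grid Positive rate grids (umol CO2 m-2 s-1).
#' @param ap TPU-limited rate (scalar; `Inf` to exclude TPU).
#' @param theta_cj,theta_cjp Curvature parameters.
#' @return Matrix of percent reductions (`length(ac_grid)` rows by
#'   `length(aj_grid)` columns), non-negative everywhere.
#' @export
reduction_surface <- function(ac_grid, aj_grid, ap = Inf,
                              theta_cj = 0.95, theta_cjp = 0.98) {
  if (any(ac_grid <= 0) || any(aj_grid <= 0) || any(ap <= 0))
    stop("rates must be positive")
  ac <- matrix(ac_grid, length(ac_grid), length(aj_grid))
  aj <- matrix(aj_grid, length(ac_grid), length(aj_grid), byrow = TRUE)
  sm <- smaller_root(theta_cj, ac, aj)
  mn <- pmin(ac, aj)
  if (is.finite(ap)) {
    sm <- smaller_root(theta_cjp, sm, ap)
    mn <- pmin(mn, ap)
  }
  100 * (mn - sm) / mn
}
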