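# Independent oracles used across the suite: kept deliberately separate
# from the package's own evaluation paths.

# The published cubic, evaluated term by term (not via the package).
oracle_cubic <- function(d) {
  -0.0001 * d^3 + 0.0912 * d^2 - 6.2162 * d + 182.1125
}

# Exact-sphere IE by direct arithmetic.
oracle_ie <- function(d) d^3 / 150^3

# Edge-cube averaging: the conventional bin factor as the mean of the
# exact IE at the two bin edges.
oracle_endpoint_factor <- function(lo, hi) (oracle_ie(lo) + oracle_ie(hi)) / 2

# E[d^3]/150^3 for d ~ U(lo, hi), closed form.
oracle_uniform_factor <- function(lo, hi) {
  (hi^4 - lo^4) / (4 * (hi - lo)) / 150^3
}

# Weighted polynomial least squares by explicit normal equations, solved
# on a rescaled diameter axis (d/300) so the cross-product matrix stays
# well conditioned, then mapped back to raw-power coefficients.
oracle_poly_fit <- function(d, y, degree, w = rep(1, length(d))) {
  s <- 300
  X <- outer(d / s, 0:degree, `^`)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1]
  beta / s^(0:degree)
}

# Simple uniform-diameter calibration generator with constant noise SD
# (homoscedastic: the regime where the ANCOVA F test is exact).
gen_flat_noise <- function(n, d_range = c(100, 250), sd0 = 150) {
  d <- runif(n, d_range[1], d_range[2])
  data.frame(diameter = d, cells = pmax(1, oracle_cubic(d) + rnorm(n, 0, sd0)))
}
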