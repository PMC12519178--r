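# Independent oracles used across test files.

# Exact ellipse perimeter by adaptive quadrature of the arc-length integral.
exact_ellipse_perimeter <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * cos(t)^2 + b^2 * sin(t)^2),
                       0, pi / 2, rel.tol = 1e-12)$value
}

# Brute-force Lin's CCC straight from the moment definitions
# (n-denominator), written independently of the package's algebra.
brute_ccc <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

# Correlated bivariate normal with equal means/SDs: its true CCC equals rho.
rbvn_pairs <- function(n, mean = 10, sd = 2, rho = 0.9) {
  z1 <- rnorm(n); z2 <- rnorm(n)
  list(x = mean + sd * z1,
       y = mean + sd * (rho * z1 + sqrt(1 - rho^2) * z2))
}
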