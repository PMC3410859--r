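# Shared fixtures and independent oracles used across the suite.

# A pure triangle curve: linear rise at slope k to load lmax, then the
# terminal drop. Built directly, not via simulate_curve().
triangle_curve <- function(k = 30, lmax = 9, step = 0.002) {
  d_y <- lmax / k
  d <- seq(0, d_y, by = step)
  if (max(d) < d_y - 1e-12) d <- c(d, d_y)
  l <- k * d
  load_displacement_curve(c(d, d_y + step, d_y + 2 * step),
                          c(l, 0.02 * lmax, 0))
}

# The published wild-type curve geometry with ductility calibrated so the
# true proportion of energy dissipated prior to fracture is 0.862.
wt_model <- function(noise_sd = 0, step = 0.002) {
  calibrate_ductility(
    curve_model(30.2, 8.9, 10.7, 6.4, step = step, noise_sd = noise_sd),
    0.862)
}

# Independent numeric-integration oracle: trapezoidal area under an
# arbitrary load function on a very fine grid.
numeric_area <- function(f, from, to, n = 200001) {
  x <- seq(from, to, length.out = n)
  y <- f(x)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Evaluate the piecewise load trajectory of a curve model at displacement x
# (mirrors the generator's documented geometry; used to cross-check the
# trapezoidal work integral against near-exact integration).
model_load_at <- function(model, x) {
  k <- model$stiffness
  d_y <- model$yield_load / k
  dl <- model$max_load - model$yield_load
  if (dl > 1e-12 && model$ductility > 0) {
    s_h <- model$ductility * 2 * dl / k
    a <- dl / s_h^2
    d_m <- d_y + s_h
    ifelse(x <= d_y, k * x, model$max_load - a * (x - d_m)^2)
  } else {
    ifelse(x <= d_y, k * x, model$fracture_load)
  }
}

# brute-force MVE criterion over all elemental subsets (independent of the
# package implementation)
brute_mve <- function(X, h) {
  n <- nrow(X); p <- ncol(X)
  subs <- combn(n, p + 1, simplify = FALSE)
  best <- NULL
  for (J in subs) {
    S <- stats::cov(X[J, , drop = FALSE])
    dt <- det(S)
    if (!is.finite(dt) || dt <= 1e-300) next
    d2 <- stats::mahalanobis(X, colMeans(X[J, , drop = FALSE]), S)
    m_h <- sort(d2)[h]
    crit <- log(dt) + p * log(m_h)
    if (is.null(best) || crit < best$crit)
      best <- list(crit = crit, subset = sort(J))
  }
  best
}
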