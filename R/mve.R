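#' Minimum volume ellipsoid estimate of location and scatter
#'
#' Robust estimate of the mean vector and covariance matrix by the minimum
#' volume ellipsoid (MVE) criterion: among ellipsoids containing at least
#' `h = floor((n + p + 1) / 2)` of the `n` observations, seek the one of
#' minimum volume. The search resamples elemental subsets of `p + 1`
#' observations; each subset's mean and covariance define an ellipsoid
#' shape, which is inflated to cover `h` points by the h-th smallest squared
#' Mahalanobis distance `m_h`, giving volume proportional to
#' `sqrt(det(S) * m_h^p)`. When `choose(n, p + 1) <= n_subsets` the
#' enumeration is exhaustive. The winning scatter is rescaled by
#' `m_h / qchisq(0.5, p)` so that squared robust distances are chi-squared
#' comparable, and by default refined by the standard one-step reweighting:
#' observations with initial squared distance within the 97.5% chi-squared
#' quantile are averaged classically, with a consistency factor for the
#' truncation, which calibrates the tail behaviour of the distances.
#' Robust estimates resist the masking effect by which a cluster of
#' outliers attracts the classical mean and inflates the classical
#' covariance so that the outliers themselves obtain small distances.
#'
#' @param X numeric matrix or data.frame, n observations x p variables
#'   (n > p >= 1).
#' @param h coverage count (default `floor((n + p + 1) / 2)`).
#' @param n_subsets maximum number of elemental subsets (default 10000).
#' @param seed RNG seed for subset sampling (ignored when exhaustive).
#' @param reweight apply the one-step reweighting (default TRUE).
#' @return Object of class `mve_fit`: `center`, `cov`, plus the raw
#'   best-subset components (`raw_center`, `raw_cov`, `best_subset`,
#'   `crit`), `h`, `n`, `p`, `n_subsets`, `exhaustive`, `seed`.
#' @export
mve_estimate <- function(X, h = NULL, n_subsets = 10000, seed = NULL,
                         reweight = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stopf("need n > p (got n=%d, p=%d)", n, p)
  h <- h %||% floor((n + p + 1) / 2)
  if (h > n || h < p + 1) stopf("h must be in [p+1, n]")
  m <- p + 1
  total <- choose(n, m)
  exhaustive <- is.finite(total) && total <= n_subsets
  subsets <- if (exhaustive) {
    combn(n, m, simplify = FALSE)
  } else {
    with_seed(seed, replicate(n_subsets, sample.int(n, m), simplify = FALSE))
  }
  best <- list(crit = Inf)
  n_sing <- 0
  for (J in subsets) {
    mu <- colMeans(X[J, , drop = FALSE])
    S <- cov(X[J, , drop = FALSE])
    dt <- suppressWarnings(det(S))
    if (!is.finite(dt) || dt <= 1e-300) { n_sing <- n_sing + 1; next }
    d2 <- tryCatch(mahalanobis(X, mu, S),
                   error = function(e) NULL)
    if (is.null(d2)) { n_sing <- n_sing + 1; next }
    m_h <- sort(d2, partial = h)[h]
    crit <- log(dt) + p * log(m_h)
    if (crit < best$crit - 1e-12) {
      best <- list(crit = crit, mu = mu, S = S, m_h = m_h, subset = J)
    }
  }
  if (!is.finite(best$crit))
    stopf("all %d elemental subsets were singular", length(subsets))
  raw_cov <- best$S * best$m_h / qchisq(0.5, p)
  center <- best$mu
  covm <- raw_cov
  if (reweight) {
    # two passes: the first cleans up the crude elemental-subset shape,
    # the second trims against the already-consistent metric
    cf <- pchisq(qchisq(0.975, p), p + 2) / 0.975
    for (pass in 1:2) {
      d2 <- mahalanobis(X, center, covm)
      w <- d2 <= qchisq(0.975, p)
      if (sum(w) <= p + 1) break
      center <- colMeans(X[w, , drop = FALSE])
      covm <- cov(X[w, , drop = FALSE]) / cf
    }
  }
  structure(
    list(center = center, cov = covm,
         raw_center = best$mu, raw_cov = raw_cov,
         best_subset = sort(best$subset), crit = best$crit, m_h = best$m_h,
         h = h, n = n, p = p, n_subsets = length(subsets),
         n_singular = n_sing, exhaustive = exhaustive, seed = seed,
         reweighted = reweight),
    class = "mve_fit"
  )
}

#' Robust Mahalanobis distances and chi-squared outlier flags
#'
#' Squared distances `d_i^2 = (x_i - mu)' Sigma^{-1} (x_i - mu)` from a
#' robust location/scatter estimate. Under multivariate normality of the
#' bulk, `d_i^2` for an inlying observation follows a chi-squared
#' distribution with p degrees of freedom, so observations with
#' `d_i^2 > qchisq(1 - alpha, p)` are flagged as outliers.
#'
#' @param X observations (n x p).
#' @param estimate an `mve_fit` (or any list with `center` and `cov`).
#' @param alpha flagging level (default 0.025).
#' @return Object of class `mahalanobis_result`: data.frame `d`, `d2`,
#'   `flag`, plus attributes `cutoff`, `alpha`, `p`.
#' @export
robust_mahalanobis <- function(X, estimate, alpha = 0.025) {
  X <- as.matrix(X)
  p <- ncol(X)
  d2 <- tryCatch(mahalanobis(X, estimate$center, estimate$cov),
                 error = function(e)
                   stopf("scatter matrix is not invertible: %s",
                         conditionMessage(e)))
  cutoff <- chi2_cutoff(p, alpha)
  out <- data.frame(d = sqrt(d2), d2 = d2, flag = d2 > cutoff)
  attr(out, "cutoff") <- cutoff
  attr(out, "alpha") <- alpha
  attr(out, "p") <- p
  class(out) <- c("mahalanobis_result", "data.frame")
  out
}

#' Chi-squared outlier cutoff
#'
#' @param p degrees of freedom (number of variables, >= 1).
#' @param alpha tail probability in (0, 1).
#' @return The `1 - alpha` quantile of the chi-squared distribution with p
#'   degrees of freedom.
#' @export
chi2_cutoff <- function(p, alpha) {
  if (p < 1) stopf("p must be >= 1")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0,1)")
  qchisq(1 - alpha, df = p)
}

#' Principal component scores for multivariate visualisation
#'
#' Centered (optionally scaled) eigendecomposition of the covariance,
#' components ordered by decreasing variance. Used to visualise multivariate
#' phenotype data and reveal outliers.
#'
#' @param X observations (n x p), n >= 2.
#' @param scale. scale variables to unit variance first (default FALSE).
#' @return List `scores` (n x p), `loadings` (p x p), `variance_fraction`
#'   (sums to 1), `sdev`.
#' @export
pca_scores <- function(X, scale. = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stopf("need n >= 2")
  pc <- prcomp(X, center = TRUE, scale. = scale.)
  list(scores = pc$x, loadings = pc$rotation,
       variance_fraction = pc$sdev^2 / sum(pc$sdev^2), sdev = pc$sdev)
}
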