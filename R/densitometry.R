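#' Grey-level histogram of bone pixels
#'
#' Counts of calibrated 8-bit grey levels (0-255) for the mineralised
#' pixels of one radiograph, with the calibration anchors (polyester and
#' steel standards, in raw units) attached when known.
#'
#' @param counts integer vector of length 256 (counts for grey levels
#'   0..255).
#' @param anchors optional list with `polyester` and `steel` raw values.
#' @param n_clipped number of raw values clipped during calibration.
#' @return Object of class `grey_histogram`.
#' @export
grey_histogram <- function(counts, anchors = NULL, n_clipped = 0L) {
  if (length(counts) != 256) stopf("counts must have length 256")
  if (any(counts < 0)) stopf("counts must be >= 0")
  if (!is.null(anchors) && anchors$polyester >= anchors$steel)
    stopf("polyester anchor must be below steel anchor")
  structure(
    list(counts = as.numeric(counts), n_pixels = sum(counts),
         anchors = anchors, n_clipped = n_clipped),
    class = "grey_histogram"
  )
}

#' Calibrate raw pixel values against phantom standards
#'
#' Linearly maps the raw (e.g. 16-bit) value of the polyester standard to
#' grey level 0 and that of the steel standard to grey level 255, rounding
#' half-up; values outside the span are clipped to the range ends and the
#' clip count reported. The calibration is affine and order-preserving.
#'
#' @param raw_values numeric vector of raw pixel values.
#' @param polyester_ref,steel_ref raw values of the standards
#'   (`polyester_ref < steel_ref`).
#' @return A [grey_histogram()].
#' @export
calibrate_grey_levels <- function(raw_values, polyester_ref, steel_ref) {
  if (polyester_ref >= steel_ref)
    stopf("polyester reference must be strictly below steel reference")
  g <- round_half_up((raw_values - polyester_ref) /
                       (steel_ref - polyester_ref) * 255)
  n_clipped <- sum(g < 0 | g > 255)
  g <- pmin(pmax(g, 0), 255)
  grey_histogram(tabulate(g + 1, nbins = 256),
                 anchors = list(polyester = polyester_ref, steel = steel_ref),
                 n_clipped = n_clipped)
}

#' Median grey level (bone mineral content summary)
#'
#' The smallest grey level whose cumulative pixel count reaches half of the
#' pixels. The median calibrated grey level of the bone pixels is the
#' screen's per-bone bone mineral content (BMC) summary.
#'
#' @param hist a [grey_histogram()].
#' @return Grey level in 0..255.
#' @export
median_grey_level <- function(hist) {
  stopifnot(inherits(hist, "grey_histogram"))
  if (hist$n_pixels < 1) stopf("empty histogram")
  cum <- cumsum(hist$counts)
  which(cum >= hist$n_pixels / 2)[1] - 1L
}

#' Cumulative frequency distribution over grey levels
#'
#' @param hist a [grey_histogram()].
#' @return Numeric vector of length 256: the ECDF evaluated at grey levels
#'   0..255 (non-decreasing, ending at 1).
#' @export
cumulative_frequency <- function(hist) {
  stopifnot(inherits(hist, "grey_histogram"))
  if (hist$n_pixels < 1) stopf("empty histogram")
  cumsum(hist$counts) / hist$n_pixels
}

#' 16-interval pseudocolor banding
#'
#' Collapses the 256 grey levels into 16 contiguous equal-width intervals
#' (half-open, width 16), the banding used to pseudocolor mineralisation
#' density. Counts are conserved.
#'
#' @param hist a [grey_histogram()].
#' @return Numeric vector of 16 bin counts; bin 1 covers grey 0-15.
#' @export
pseudocolor_bins <- function(hist) {
  stopifnot(inherits(hist, "grey_histogram"))
  bin <- (0:255) %/% 16 + 1
  as.numeric(tapply(hist$counts, bin, sum))
}

#' Two-sample Kolmogorov-Smirnov comparison of grey-level histograms
#'
#' D is the maximum absolute difference between the two cumulative
#' frequency distributions evaluated at the grey-level bin edges, reported
#' in percent (0-100). Significance bands compare D with [ks_critical()] at
#' alpha = 0.05, 0.01 and 0.001 for the two pixel counts.
#'
#' @param hist_a,hist_b [grey_histogram()] objects.
#' @return List `D` (percent), `significance` (one of `"ns"`, `"P<0.05"`,
#'   `"P<0.01"`, `"P<0.001"`), `critical` (named vector of the three
#'   thresholds).
#' @export
ks_two_sample <- function(hist_a, hist_b) {
  fa <- cumulative_frequency(hist_a)
  fb <- cumulative_frequency(hist_b)
  D <- 100 * max(abs(fa - fb))
  crit <- c(`0.05` = ks_critical(0.05, hist_a$n_pixels, hist_b$n_pixels),
            `0.01` = ks_critical(0.01, hist_a$n_pixels, hist_b$n_pixels),
            `0.001` = ks_critical(0.001, hist_a$n_pixels, hist_b$n_pixels))
  sig <- if (D > crit["0.001"]) "P<0.001"
         else if (D > crit["0.01"]) "P<0.01"
         else if (D > crit["0.05"]) "P<0.05"
         else "ns"
  list(D = D, significance = sig, critical = crit)
}

#' Critical value of the two-sample KS statistic (percent scale)
#'
#' `D_crit = 100 * c(alpha) * sqrt((n + m) / (n * m))`, with the tabled
#' coefficients c = 1.36, 1.63 and 1.95 at alpha = 0.05, 0.01 and 0.001 (at
#' n = m = 1024 pixels these give the thresholds 6.01, 7.20 and 8.62) and
#' the asymptotic coefficient `sqrt(-ln(alpha/2)/2)` for other levels.
#'
#' @param alpha significance level.
#' @param n,m the two sample sizes (pixel counts).
#' @return Critical D in percent.
#' @export
ks_critical <- function(alpha, n, m) {
  if (n < 1 || m < 1) stopf("sample sizes must be >= 1")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0,1)")
  tabled <- c(`0.05` = 1.36, `0.01` = 1.63, `0.001` = 1.95)
  key <- names(tabled)[vapply(as.numeric(names(tabled)),
                              function(a) isTRUE(all.equal(a, alpha)),
                              logical(1))]
  cc <- if (length(key)) tabled[[key]] else sqrt(-log(alpha / 2) / 2)
  100 * cc * sqrt((n + m) / (n * m))
}

#' Simulate a grey-level histogram with a prescribed median
#'
#' Draws `n_pixels` grey levels from a discretised normal centred on the
#' target, then shifts and adjusts pixel-by-pixel so the median grey level
#' (under the cumulative-count rule of [median_grey_level()]) is exactly
#' `target_median`.
#'
#' @param target_median integer grey level in 0..255.
#' @param n_pixels number of pixels (default 1024).
#' @param spread SD of the underlying normal, grey levels.
#' @param seed RNG seed.
#' @return A [grey_histogram()].
#' @export
simulate_grey_histogram <- function(target_median, n_pixels = 1024,
                                    spread = 20, seed = NULL) {
  if (target_median < 0 || target_median > 255)
    stopf("target_median must be in 0..255")
  if (n_pixels < 1) stopf("n_pixels must be >= 1")
  v <- with_seed(seed, round_half_up(rnorm(n_pixels, target_median, spread)))
  v <- pmin(pmax(v, 0), 255)
  med_of <- function(x) {
    cnt <- tabulate(x + 1, nbins = 256)
    which(cumsum(cnt) >= length(x) / 2)[1] - 1L
  }
  v <- pmin(pmax(v + (target_median - med_of(v)), 0), 255)
  guard <- 0
  while (med_of(v) != target_median && guard < 1024) {
    m <- med_of(v)
    if (m > target_median) {
      # move one pixel from above the target down onto it
      i <- which(v > target_median)[1]
    } else {
      i <- which(v < target_median)[1]
    }
    v[i] <- target_median
    guard <- guard + 1
  }
  grey_histogram(tabulate(v + 1, nbins = 256))
}
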