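#' Locate the linear elastic region of a load-displacement curve
#'
#' Slides every contiguous window of at least `min_span` samples over the
#' rising limb (samples with load between `load_lo` and `load_hi` times the
#' maximum load, before the peak) and returns the window with the highest
#' linear-fit R-squared. Ties (e.g. an exactly linear limb) are broken in
#' favour of the widest, then earliest, window.
#'
#' @param curve an `ld_curve`.
#' @param min_span minimum number of samples in the window.
#' @param load_lo,load_hi candidate band as fractions of the maximum load.
#' @return List with `start`, `end` (sample indices), `r_squared`.
#' @export
find_elastic_region <- function(curve, min_span = 10,
                                load_lo = 0.10, load_hi = 0.80) {
  stopifnot(inherits(curve, "ld_curve"))
  d <- curve$displacement_mm
  l <- curve$load_N
  peak <- which.max(l)
  lmax <- l[peak]
  i0 <- which(l[seq_len(peak)] >= load_lo * lmax)[1]
  pre <- seq_len(peak)
  i1 <- max(pre[l[pre] <= load_hi * lmax & pre >= i0], i0)
  n_band <- i1 - i0 + 1
  if (is.na(i0) || n_band < min_span)
    stopf("no pre-peak window of at least %d samples in the %g-%g load band",
          min_span, load_lo, load_hi)
  x <- d[i0:i1]
  y <- l[i0:i1]
  # prefix sums give O(1) OLS statistics per window
  cx <- c(0, cumsum(x)); cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x^2)); cyy <- c(0, cumsum(y^2)); cxy <- c(0, cumsum(x * y))
  starts <- rep(seq_len(n_band), times = n_band) # over local indices
  ends <- rep(seq_len(n_band), each = n_band)
  keep <- ends - starts + 1 >= min_span
  starts <- starts[keep]; ends <- ends[keep]
  n <- ends - starts + 1
  sx <- cx[ends + 1] - cx[starts]
  sy <- cy[ends + 1] - cy[starts]
  sxx <- cxx[ends + 1] - cxx[starts]
  syy <- cyy[ends + 1] - cyy[starts]
  sxy <- cxy[ends + 1] - cxy[starts]
  ssxx <- sxx - sx^2 / n
  ssyy <- syy - sy^2 / n
  ssxy <- sxy - sx * sy / n
  r2 <- ifelse(ssxx > 0 & ssyy > 0, ssxy^2 / (ssxx * ssyy), -Inf)
  best_r2 <- max(r2)
  tied <- which(r2 >= best_r2 - 1e-9)
  tied <- tied[order(-n[tied], starts[tied])][1]
  list(start = i0 + starts[tied] - 1, end = i0 + ends[tied] - 1,
       r_squared = best_r2)
}

#' Fit stiffness over the elastic region
#'
#' Ordinary least-squares slope of load on displacement over the region
#' found by [find_elastic_region()].
#'
#' @param curve an `ld_curve`.
#' @param region list with `start`/`end` indices (from
#'   [find_elastic_region()]); located automatically when `NULL`.
#' @return List of class `elastic_fit`: `stiffness` (N/mm), `intercept`,
#'   `sigma` (residual SD), `region`, `r_squared`.
#' @export
fit_stiffness <- function(curve, region = NULL) {
  stopifnot(inherits(curve, "ld_curve"))
  if (is.null(region)) region <- find_elastic_region(curve)
  idx <- region$start:region$end
  x <- curve$displacement_mm[idx]
  y <- curve$load_N[idx]
  if (var(x) <= 0) stopf("zero displacement variance in elastic region")
  slope <- cov(x, y) / var(x)
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sigma <- if (length(idx) > 2) sqrt(sum(resid^2) / (length(idx) - 2)) else 0
  structure(
    list(stiffness = slope, intercept = intercept, sigma = sigma,
         region = region, r_squared = region$r_squared %||% NA_real_),
    class = "elastic_fit"
  )
}

#' Maximum and fracture load
#'
#' `detect_max()` returns the global maximum load. `detect_fracture()`
#' applies a terminal-drop rule: the fracture load is the load at the last
#' sample before the record first falls below `drop_frac` of the maximum
#' load; a record with no such drop is assigned its final load and flagged.
#'
#' @param curve an `ld_curve`.
#' @param drop_frac drop threshold as a fraction of the maximum load.
#' @return `detect_max()`: list `load`, `index`. `detect_fracture()`: list
#'   `load`, `index`, `no_drop` (flag).
#' @export
detect_max <- function(curve) {
  stopifnot(inherits(curve, "ld_curve"))
  i <- which.max(curve$load_N)
  list(load = curve$load_N[i], index = i)
}

#' @rdname detect_max
#' @export
detect_fracture <- function(curve, drop_frac = 0.10) {
  stopifnot(inherits(curve, "ld_curve"))
  l <- curve$load_N
  peak <- which.max(l)
  post <- seq(peak, length(l))
  below <- post[l[post] < drop_frac * l[peak]]
  if (length(below) == 0 || below[1] == 1) {
    return(list(load = tail(l, 1), index = length(l), no_drop = TRUE))
  }
  i <- below[1] - 1
  list(load = l[i], index = i, no_drop = FALSE)
}

#' Detect the yield load
#'
#' Scans the rising limb after the start of the elastic region for the first
#' run of `persistence` consecutive samples whose load falls below
#' `fraction` of the elastic-line prediction (the secant-deviation
#' criterion). With `refine = TRUE` (default) the crossing is then walked
#' back to the point of departure from the elastic fit -- the last earlier
#' sample whose smoothed load is within `max(3 x smoothed residual SD,
#' tol_rel x prediction)` of the prediction -- which on clean curves
#' recovers the true onset of plasticity rather than the later point at
#' which the deviation reaches 5%. A curve with no deviation before the peak yields at the
#' maximum load and is flagged.
#'
#' @param curve an `ld_curve`.
#' @param fit an `elastic_fit` (or numeric stiffness, intercept 0).
#' @param fraction secant threshold (default 0.95).
#' @param persistence consecutive sub-threshold samples required.
#' @param refine walk back to the departure point (default TRUE).
#' @param tol_rel relative departure tolerance used by the refinement.
#' @param smooth half-width of the running-mean smoother used for detection.
#' @return List `load`, `index`, `at_max` (flag).
#' @export
detect_yield <- function(curve, fit, fraction = 0.95, persistence = 5,
                         refine = TRUE, tol_rel = 2e-5, smooth = 2) {
  stopifnot(inherits(curve, "ld_curve"))
  if (is.numeric(fit)) {
    if (fit <= 0) stopf("stiffness must be > 0")
    fit <- list(stiffness = fit, intercept = 0, sigma = 0,
                region = list(start = 1, end = 1))
  }
  l <- curve$load_N
  d <- curve$displacement_mm
  peak <- which.max(l)
  start <- fit$region$start
  if (peak <= start)
    return(list(load = l[peak], index = peak, at_max = TRUE))
  # light smoothing for detection only
  ls <- if (smooth > 0) {
    w <- 2 * smooth + 1
    as.numeric(stats::filter(l, rep(1 / w, w), sides = 2))
  } else l
  ls[is.na(ls)] <- l[is.na(ls)]
  pred <- fit$intercept + fit$stiffness * d
  idx <- seq(start + 1, peak)
  below <- ls[idx] < fraction * pred[idx]
  run <- 0
  cross <- NA_integer_
  for (j in seq_along(below)) {
    run <- if (isTRUE(below[j])) run + 1 else 0
    if (run >= persistence) {
      cross <- idx[j] - persistence + 1
      break
    }
  }
  if (is.na(cross))
    return(list(load = l[peak], index = peak, at_max = TRUE))
  i <- cross
  if (refine) {
    tol <- pmax(3 * (fit$sigma %||% 0), tol_rel * pred)
    while (i > start + 1 && l[i - 1] < pred[i - 1] - tol[i - 1]) i <- i - 1
    i <- max(i - 1, start)   # last sample still on the elastic line
  }
  list(load = l[i], index = i, at_max = FALSE)
}

#' Work energy under the curve
#'
#' Trapezoidal area under load versus displacement from the start of the
#' record to the stated endpoint (the maximum-load or the fracture sample).
#'
#' @param curve an `ld_curve`.
#' @param endpoint `"max"`, `"fracture"`, or a sample index.
#' @param drop_frac passed to [detect_fracture()] when
#'   `endpoint = "fracture"`.
#' @return Energy in N.mm.
#' @export
work_energy <- function(curve, endpoint = c("max", "fracture"),
                        drop_frac = 0.10) {
  stopifnot(inherits(curve, "ld_curve"))
  if (is.character(endpoint)) {
    endpoint <- match.arg(endpoint)
    end <- switch(endpoint,
                  max = detect_max(curve)$index,
                  fracture = detect_fracture(curve, drop_frac)$index)
  } else {
    end <- endpoint
  }
  d <- curve$displacement_mm[seq_len(end)]
  l <- curve$load_N[seq_len(end)]
  sum(diff(d) * (head(l, -1) + tail(l, -1)) / 2)
}

#' Elastic stored energy at a point on the curve
#'
#' Area of the right triangle with its vertex at the point of interest and
#' hypotenuse of slope equal to the elastic stiffness: `load^2 / (2 *
#' stiffness)`. This is the recoverable energy released if the bone unloaded
#' elastically from that point.
#'
#' @param load load at the point, N.
#' @param stiffness elastic stiffness, N/mm (> 0).
#' @return Energy in N.mm.
#' @export
elastic_stored_energy <- function(load, stiffness) {
  if (any(stiffness <= 0)) stopf("stiffness must be > 0")
  load^2 / (2 * stiffness)
}

#' Dissipated energy and its proportion
#'
#' Dissipated energy is the work energy minus the elastic stored energy at
#' the same point; measurement noise can make the difference marginally
#' negative, in which case it is clipped to zero and flagged. The proportion
#' DE / (DE + ESE) equals DE / work and quantifies ductility.
#'
#' @param work work energy, N.mm (>= 0).
#' @param ese elastic stored energy, N.mm (>= 0).
#' @return List `de`, `proportion`, `clipped`.
#' @export
dissipated_energy <- function(work, ese) {
  if (work < 0 || ese < 0) stopf("energies must be >= 0")
  if (work == 0 && ese == 0)
    stopf("proportion dissipated undefined: work and ESE both zero")
  de <- work - ese
  clipped <- de < 0
  de <- max(de, 0)
  if (clipped)
    warning("negative dissipated energy clipped to 0", call. = FALSE)
  list(de = de, proportion = de / max(work, de + ese), clipped = clipped)
}

#' Angular transformation of a proportion
#'
#' The classical variance-stabilising transform for proportions,
#' `arcsin(sqrt(p))`.
#'
#' @param p proportion(s) in \[0, 1\].
#' @param degrees return degrees instead of radians.
#' @return Transformed value(s).
#' @export
angular_transform <- function(p, degrees = FALSE) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("proportions must be in [0,1]")
  out <- asin(sqrt(p))
  if (degrees) out * 180 / pi else out
}

#' Decompose a load-displacement curve into the six biomechanical parameters
#'
#' Runs the full analysis chain -- elastic region selection, least-squares
#' stiffness, yield/maximum/fracture load detection, work energies by
#' trapezoidal integration, elastic stored energy triangles and the
#' dissipated-energy partition at maximum load and at fracture.
#'
#' @param curve an `ld_curve`.
#' @param config optional named list overriding defaults: `min_span`,
#'   `load_lo`, `load_hi`, `yield_fraction`, `yield_refine`, `drop_frac`,
#'   `angular_degrees`.
#' @return A one-row data.frame of class `biomech_profile` with the loads,
#'   stiffness, energies, proportions, angular-transformed proportions, the
#'   elastic-fit R-squared and flag columns.
#' @export
analyze_curve <- function(curve, config = list()) {
  stopifnot(inherits(curve, "ld_curve"))
  cfg <- modifyList(list(min_span = 10, load_lo = 0.10, load_hi = 0.80,
                         yield_fraction = 0.95, yield_refine = TRUE,
                         drop_frac = 0.10, angular_degrees = FALSE), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("analyze_curve failed at stage '%s': %s", name, conditionMessage(e)))
  }
  region <- stage("elastic_region",
                  find_elastic_region(curve, cfg$min_span, cfg$load_lo, cfg$load_hi))
  fit <- stage("stiffness", fit_stiffness(curve, region))
  mx <- stage("max", detect_max(curve))
  yld <- stage("yield",
               detect_yield(curve, fit, fraction = cfg$yield_fraction,
                            refine = cfg$yield_refine))
  fr <- stage("fracture", detect_fracture(curve, cfg$drop_frac))
  w_ml <- stage("work_ml", work_energy(curve, mx$index))
  w_f <- stage("work_f", work_energy(curve, fr$index))
  ese_ml <- elastic_stored_energy(mx$load, fit$stiffness)
  ese_f <- elastic_stored_energy(fr$load, fit$stiffness)
  de_ml <- suppressWarnings(dissipated_energy(w_ml, ese_ml))
  de_f <- suppressWarnings(dissipated_energy(w_f, ese_f))
  out <- data.frame(
    yield_load = yld$load,
    max_load = mx$load,
    fracture_load = fr$load,
    stiffness = fit$stiffness,
    work_ml = w_ml, work_f = w_f,
    ese_ml = ese_ml, ese_f = ese_f,
    de_ml = de_ml$de, de_f = de_f$de,
    prop_de_ml = de_ml$proportion,
    prop_de_f = de_f$proportion,
    ang_prop_de_ml = angular_transform(de_ml$proportion, cfg$angular_degrees),
    ang_prop_de_f = angular_transform(de_f$proportion, cfg$angular_degrees),
    elastic_r_squared = region$r_squared,
    flag_yield_at_max = yld$at_max,
    flag_no_drop = fr$no_drop,
    flag_de_clipped = de_ml$clipped || de_f$clipped
  )
  class(out) <- c("biomech_profile", "data.frame")
  out
}

#' Analyze a batch of curves
#'
#' @param curves a list of `ld_curve` objects (or a directory of two-column
#'   delimited curve files).
#' @param config passed to [analyze_curve()].
#' @return A data.frame with one `biomech_profile` row per curve; row order
#'   follows the input, with an `id` column from list names or file names.
#' @export
analyze_curves <- function(curves, config = list()) {
  if (is.character(curves) && length(curves) == 1 && dir.exists(curves)) {
    files <- list.files(curves, full.names = TRUE)
    nm <- tools::file_path_sans_ext(basename(files))
    curves <- lapply(files, read_curve)
    names(curves) <- nm
  }
  ids <- names(curves) %||% as.character(seq_along(curves))
  if (is.null(names(curves))) ids <- as.character(seq_along(curves))
  rows <- lapply(curves, analyze_curve, config = config)
  out <- do.call(rbind, rows)
  out <- cbind(id = ids, out)
  rownames(out) <- NULL
  out
}
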