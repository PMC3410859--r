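#' Parametric model of a destructive 3-point bend test curve
#'
#' Describes the idealised load-displacement trajectory of one bone: a
#' linear elastic phase of slope `stiffness` up to the yield load, a
#' quadratic hardening arc rising to the maximum load, the descending branch
#' of the same parabola down to the fracture load, and a terminal drop at
#' fracture. The `ductility` parameter scales the half-span of the parabola
#' (1 = the span at which the arc meets the elastic phase with a continuous
#' slope); larger values lengthen the post-yield phase and so increase the
#' proportion of energy dissipated prior to fracture.
#'
#' @param stiffness slope of the elastic phase, N/mm (> 0).
#' @param yield_load load at onset of plastic deformation, N.
#' @param max_load peak load, N (>= yield_load).
#' @param fracture_load load at failure, N (<= max_load).
#' @param ductility non-negative span multiplier for the post-yield parabola.
#' @param step displacement sampling step, mm.
#' @param noise_sd SD of additive Gaussian load noise, N.
#' @return An object of class `curve_model`.
#' @export
curve_model <- function(stiffness, yield_load, max_load, fracture_load,
                        ductility = 1, step = 0.002, noise_sd = 0) {
  if (stiffness <= 0) stopf("stiffness must be > 0 (got %g)", stiffness)
  if (yield_load <= 0 || yield_load > max_load + 1e-12)
    stopf("need 0 < yield_load <= max_load (got %g, %g)", yield_load, max_load)
  if (fracture_load <= 0 || fracture_load > max_load + 1e-12)
    stopf("need 0 < fracture_load <= max_load (got %g, %g)",
          fracture_load, max_load)
  if (ductility < 0) stopf("ductility must be >= 0")
  if (step <= 0) stopf("sampling step must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(
    list(stiffness = stiffness, yield_load = yield_load,
         max_load = max_load, fracture_load = fracture_load,
         ductility = ductility, step = step, noise_sd = noise_sd),
    class = "curve_model"
  )
}

# piecewise geometry shared by the sampler and the analytic energies
curve_geometry <- function(model) {
  k <- model$stiffness
  ly <- model$yield_load
  lm <- model$max_load
  lf <- model$fracture_load
  d_y <- ly / k
  dl <- lm - ly
  if (dl > 1e-12 && model$ductility > 0) {
    s0 <- 2 * dl / k                      # slope-continuous half-span
    s_h <- model$ductility * s0
    a <- dl / s_h^2
    d_m <- d_y + s_h
    d_f <- if (lm - lf > 1e-12) d_m + sqrt((lm - lf) / a) else d_m
  } else {
    # degenerate: no hardening arc (yield = max or zero ductility)
    s_h <- 0
    a <- NA_real_
    d_m <- d_y
    d_f <- d_m
  }
  list(d_y = d_y, d_m = d_m, d_f = d_f, a = a, s_h = s_h)
}

# analytic work energy and energy partition implied by a curve_model
#' True energies of a curve model
#'
#' Closed-form work energy to maximum load and to fracture, elastic stored
#' energies, and dissipated-energy proportions implied by the piecewise
#' geometry of a [curve_model()] (no sampling, no noise).
#'
#' @param model a [curve_model()].
#' @return Named list with `work_ml`, `work_f`, `ese_ml`, `ese_f`,
#'   `prop_de_ml`, `prop_de_f`.
#' @export
curve_model_energies <- function(model) {
  g <- curve_geometry(model)
  k <- model$stiffness
  elastic <- model$yield_load^2 / (2 * k)
  if (g$s_h > 0) {
    # integral of L_max - a (x - d_m)^2 between x1 and x2
    arc <- function(x1, x2) {
      model$max_load * (x2 - x1) -
        g$a / 3 * ((x2 - g$d_m)^3 - (x1 - g$d_m)^3)
    }
    work_ml <- elastic + arc(g$d_y, g$d_m)
    work_f <- elastic + arc(g$d_y, g$d_f)
  } else {
    work_ml <- elastic
    work_f <- elastic
  }
  ese_ml <- model$max_load^2 / (2 * k)
  ese_f <- model$fracture_load^2 / (2 * k)
  list(
    work_ml = work_ml, work_f = work_f, ese_ml = ese_ml, ese_f = ese_f,
    prop_de_ml = max(work_ml - ese_ml, 0) / work_ml,
    prop_de_f = max(work_f - ese_f, 0) / work_f
  )
}

#' Calibrate the ductility parameter to a target dissipated proportion
#'
#' Solves for the ductility multiplier at which the model's true proportion
#' of energy dissipated prior to fracture equals `target`. The proportion is
#' strictly increasing in ductility, with infimum `1 - (L_f/L_y)^2 *
#' (work ratio)` at zero ductility, so the root is unique when reachable.
#'
#' @param model a [curve_model()]; its `ductility` field is ignored.
#' @param target desired proportion of energy dissipated prior to fracture,
#'   in (0, 1).
#' @param interval search interval for the multiplier.
#' @return The calibrated [curve_model()].
#' @export
calibrate_ductility <- function(model, target, interval = c(1e-6, 200)) {
  if (target <= 0 || target >= 1) stopf("target proportion must be in (0,1)")
  prop_at <- function(eta) {
    m <- model
    m$ductility <- eta
    curve_model_energies(m)$prop_de_f - target
  }
  lo <- prop_at(interval[1])
  hi <- prop_at(interval[2])
  if (lo >= 0) {
    if (lo > 1e-6)
      stopf("target %.3f below the minimum reachable proportion %.3f",
            target, target + lo)
    model$ductility <- interval[1]   # target sits on the interval edge
    return(model)
  }
  if (hi < 0)
    stopf("target %.3f not reachable within ductility interval", target)
  eta <- uniroot(prop_at, interval, tol = 1e-10)$root
  model$ductility <- eta
  model
}

#' Simulate a load-displacement curve
#'
#' Samples the piecewise trajectory of a [curve_model()] on a regular
#' displacement grid, appends the terminal drop at fracture, and adds
#' Gaussian load noise. Loads are clamped at zero so the record is
#' physically admissible.
#'
#' @param model a [curve_model()].
#' @param seed optional RNG seed for the noise (restores caller RNG state).
#' @return A [load_displacement_curve()] with the model attached as
#'   attribute `"model"`.
#' @export
simulate_curve <- function(model, seed = NULL) {
  stopifnot(inherits(model, "curve_model"))
  g <- curve_geometry(model)
  step <- model$step
  d <- seq(0, g$d_f, by = step)
  if (tail(d, 1) < g$d_f - 1e-12) d <- c(d, g$d_f)
  load <- ifelse(
    d <= g$d_y + 1e-15,
    model$stiffness * d,
    model$max_load - g$a * (d - g$d_m)^2
  )
  if (g$s_h == 0) {          # pure triangle: no post-yield samples
    load[d > g$d_y + 1e-15] <- model$fracture_load
  }
  # terminal drop: one sample near zero load, one at zero
  d <- c(d, g$d_f + step, g$d_f + 2 * step)
  load <- c(load, 0.02 * model$max_load, 0)
  if (model$noise_sd > 0) {
    load <- with_seed(seed, load + rnorm(length(load), 0, model$noise_sd))
    load <- pmax(load, 0)
  }
  curve <- load_displacement_curve(d, load)
  attr(curve, "model") <- model
  curve
}

#' Construct a load-displacement curve
#'
#' @param displacement displacement samples, mm; non-decreasing, first >= 0.
#' @param load load samples, N; same length as `displacement`.
#' @param metadata optional named list (mouse id, bone, span, rate, ...).
#' @return A data.frame of class `ld_curve` with columns `displacement_mm`
#'   and `load_N`.
#' @export
load_displacement_curve <- function(displacement, load, metadata = list()) {
  if (length(displacement) != length(load))
    stopf("displacement and load must have equal length")
  if (length(displacement) < 10)
    stopf("a load-displacement curve needs >= 10 samples (got %d)",
          length(displacement))
  if (any(!is.finite(displacement)) || any(!is.finite(load)))
    stopf("non-finite values in curve")
  if (displacement[1] < 0) stopf("first displacement must be >= 0")
  if (any(diff(displacement) < -1e-12))
    stopf("displacement must be non-decreasing")
  structure(
    data.frame(displacement_mm = displacement, load_N = load),
    metadata = metadata,
    class = c("ld_curve", "data.frame")
  )
}

#' Read/write a curve as two-column delimited text
#'
#' Files have a header line `displacement_mm<TAB>load_N`.
#'
#' @param path file path.
#' @param curve an `ld_curve`.
#' @return `read_curve()` returns an `ld_curve`; `write_curve()` the path,
#'   invisibly.
#' @export
read_curve <- function(path) {
  tab <- read.delim(path, header = TRUE)
  need <- c("displacement_mm", "load_N")
  if (!all(need %in% names(tab)))
    stopf("curve file %s lacks columns %s", path,
          paste(setdiff(need, names(tab)), collapse = ", "))
  load_displacement_curve(tab$displacement_mm, tab$load_N)
}

#' @rdname read_curve
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ld_curve"))
  write.table(as.data.frame(curve), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
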