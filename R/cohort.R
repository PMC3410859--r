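#' Specification of a synthetic cohort
#'
#' Collects the population moments, cross-parameter correlation and sizes
#' used by the synthetic generators: a wild-type reference cohort of `n_wt`
#' mice and `n_strains` knockout strains of 2-6 mice each, mirroring the
#' design of the screen this package implements.
#'
#' @param n_wt wild-type reference cohort size (default 77).
#' @param n_strains number of knockout strains (default 100).
#' @param mice_per_strain integer range (min, max) of mice per strain.
#' @param parameters data.frame with columns `parameter`, `mean`, `sd`
#'   (default [wt_parameter_defaults()]).
#' @param correlation correlation matrix over the parameters (default
#'   [default_correlation()]).
#' @param seed RNG seed attached to the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_wt = 77, n_strains = 100,
                        mice_per_strain = c(2, 6),
                        parameters = wt_parameter_defaults(),
                        correlation = default_correlation(),
                        seed = 1L) {
  stopifnot(n_wt >= 1, n_strains >= 0)
  if (any(mice_per_strain < 1) || mice_per_strain[1] > mice_per_strain[2])
    stopf("mice_per_strain must be an increasing range of counts >= 1")
  if (any(parameters$sd < 0)) stopf("parameter SDs must be >= 0")
  p <- nrow(parameters)
  if (!all(dim(correlation) == c(p, p)))
    stopf("correlation must be %d x %d", p, p)
  if (max(abs(correlation - t(correlation))) > 1e-10)
    stopf("correlation matrix must be symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-10)
    stopf("correlation matrix must have unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stopf("correlation matrix is not positive semi-definite (min eigenvalue %g)",
          min(ev))
  structure(
    list(n_wt = n_wt, n_strains = n_strains,
         mice_per_strain = as.integer(mice_per_strain),
         parameters = parameters, correlation = correlation,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# multivariate-normal rows for `n` mice, with optional mean shift in SD units
draw_mice <- function(spec, n, shift_sd = 0) {
  mu <- spec$parameters$mean
  s <- spec$parameters$sd
  Sigma <- diag(s) %*% spec$correlation %*% diag(s)
  X <- MASS::mvrnorm(n, mu + shift_sd * s, Sigma)
  X <- matrix(X, nrow = n)
  colnames(X) <- spec$parameters$parameter
  as.data.frame(X)
}

#' Simulate the wild-type reference cohort
#'
#' Draws `n_wt` mice from a multivariate normal with the spec's moments and
#' correlation. Deterministic under a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed; defaults to the spec's seed.
#' @return Data.frame with `mouse` and `strain` (= `"WT"`) columns plus one
#'   column per parameter.
#' @export
simulate_wt_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  tab <- with_seed(seed, draw_mice(spec, spec$n_wt))
  cbind(mouse = sprintf("WT%03d", seq_len(spec$n_wt)), strain = "WT", tab,
        stringsAsFactors = FALSE)
}

#' Planted phenotype categories
#'
#' The four functional categories of bone strength used by the screen, with
#' default effect-size patterns in wild-type SD units. Weak categories shift
#' the load parameters and BMC down; the strong category shifts them up;
#' brittle categories shift the proportion of energy dissipated prior to
#' fracture down; `normal` plants no effect.
#'
#' @param category one of `"normal"`, `"weak_flexible_lowBMC"`,
#'   `"weak_brittle_lowBMC"`, `"strong_brittle_highBMC"`.
#' @param magnitude scale factor applied to the unit pattern (SD units).
#' @param effects optional named numeric vector overriding the default
#'   pattern entirely (parameter -> shift in SD units).
#' @return Object of class `planted_phenotype`.
#' @export
planted_phenotype <- function(category = c("normal", "weak_flexible_lowBMC",
                                           "weak_brittle_lowBMC",
                                           "strong_brittle_highBMC"),
                              magnitude = 4, effects = NULL) {
  category <- match.arg(category)
  if (is.null(effects)) {
    unit <- switch(category,
      normal = c(),
      weak_flexible_lowBMC = c(
        max_load = -1, yield_load = -1, fracture_load = -0.75,
        stiffness = -0.5, bmc = -1, cort_th = -0.5),
      weak_brittle_lowBMC = c(
        max_load = -1, yield_load = -1, fracture_load = -0.5,
        stiffness = -0.75, bmc = -1, cort_th = -0.5,
        prop_de_f = -1, prop_de_ml = -0.75),
      strong_brittle_highBMC = c(
        max_load = 1, yield_load = 1, fracture_load = 0.5,
        stiffness = 0.5, bmc = 1, cort_th = 0.75,
        prop_de_f = -1, prop_de_ml = -0.75)
    )
    effects <- unit * magnitude
  }
  if (category == "normal" && length(effects) && any(effects != 0))
    stopf("category 'normal' requires all effect sizes 0")
  structure(list(category = category, effects = effects),
            class = "planted_phenotype")
}

#' Simulate one knockout strain with a planted phenotype
#'
#' Rows are drawn as wild type plus the phenotype's per-parameter shifts (in
#' WT SD units). The planted category travels with the table as the truth
#' label for recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @param phenotype a [planted_phenotype()].
#' @param n_mice number of mice; must lie in the spec's range.
#' @param strain strain id.
#' @param seed RNG seed.
#' @return Data.frame of mice with attribute `"truth"` = category.
#' @export
simulate_ko_strain <- function(spec, phenotype, n_mice,
                               strain = "KO", seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(phenotype, "planted_phenotype"))
  if (n_mice < spec$mice_per_strain[1] || n_mice > spec$mice_per_strain[2])
    stopf("n_mice %d outside the spec range %d-%d", n_mice,
          spec$mice_per_strain[1], spec$mice_per_strain[2])
  shift <- setNames(numeric(nrow(spec$parameters)), spec$parameters$parameter)
  bad <- setdiff(names(phenotype$effects), names(shift))
  if (length(bad)) stopf("unknown parameters in effects: %s",
                         paste(bad, collapse = ", "))
  shift[names(phenotype$effects)] <- phenotype$effects
  tab <- with_seed(seed, draw_mice(spec, n_mice, shift_sd = shift))
  out <- cbind(mouse = sprintf("%s_%02d", strain, seq_len(n_mice)),
               strain = strain, tab, stringsAsFactors = FALSE)
  attr(out, "truth") <- phenotype$category
  out
}

#' Simulate a full knockout cohort with planted truth labels
#'
#' Generates `spec$n_strains` strains; `planted` assigns a category to named
#' strain indices (all others are `normal`). Strain sizes are drawn
#' uniformly from the spec's range.
#'
#' @param spec a [cohort_spec()].
#' @param planted named list mapping strain index (as character) or a vector
#'   of categories of length `n_strains`.
#' @param magnitude planted effect magnitude in SD units.
#' @param seed RNG seed; defaults to the spec's seed + 1.
#' @return List with `mice` (per-mouse table) and `truth` (data.frame
#'   strain/category).
#' @export
simulate_ko_cohort <- function(spec = cohort_spec(), planted = list(),
                               magnitude = 4, seed = spec$seed + 1L) {
  cats <- rep("normal", spec$n_strains)
  if (length(planted)) {
    idx <- as.integer(names(planted))
    cats[idx] <- unlist(planted)
  }
  with_seed(seed, {
    sizes <- sample(seq(spec$mice_per_strain[1], spec$mice_per_strain[2]),
                    spec$n_strains, replace = TRUE)
    tabs <- lapply(seq_len(spec$n_strains), function(i) {
      simulate_ko_strain(spec, planted_phenotype(cats[i], magnitude),
                         sizes[i], strain = sprintf("KO%03d", i))
    })
    list(
      mice = do.call(rbind, tabs),
      truth = data.frame(strain = sprintf("KO%03d", seq_len(spec$n_strains)),
                         category = cats, n_mice = sizes,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Build curve models for a cohort table
#'
#' Maps each mouse's drawn biomechanical phenotype (stiffness, yield,
#' maximum and fracture loads, proportion of energy dissipated prior to
#' fracture) onto a [curve_model()], calibrating the ductility parameter per
#' mouse so the model's true dissipated proportion matches the drawn value.
#' Load ordering constraints are enforced by clamping the rare draws that
#' violate them (yield and fracture at most the maximum load), and the
#' proportion target is clamped just above its geometric lower bound.
#'
#' @param cohort per-mouse table with the biomechanical parameter columns.
#' @param step,noise_sd sampling step (mm) and load noise SD (N) given to
#'   every model.
#' @return List of `curve_model` objects, named by mouse id.
#' @export
cohort_curve_models <- function(cohort, step = 0.002, noise_sd = 0.03) {
  need <- c("stiffness", "yield_load", "max_load", "fracture_load",
            "prop_de_f")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stopf("cohort lacks columns: %s", paste(miss, collapse = ", "))
  models <- lapply(seq_len(nrow(cohort)), function(i) {
    k <- max(cohort$stiffness[i], 1e-3)
    lmax <- max(cohort$max_load[i], 0.1)
    ly <- min(max(cohort$yield_load[i], 0.05), 0.995 * lmax)
    lf <- min(max(cohort$fracture_load[i], 0.05), lmax)
    target <- min(max(cohort$prop_de_f[i], 0.02), 0.98)
    # a ductility below 1 would make the hardening arc rise above the
    # elastic line (slope at yield > stiffness); keep the geometry
    # physical by raising the fracture load until the target proportion
    # is reachable at ductility >= 1
    prop_at_eta1 <- function(lf_try) {
      curve_model_energies(curve_model(k, ly, lmax, lf_try,
                                       ductility = 1))$prop_de_f
    }
    if (prop_at_eta1(lf) > target) {
      hi <- 0.999 * lmax
      if (prop_at_eta1(hi) > target) {
        lf <- hi
        target <- prop_at_eta1(hi) + 1e-6
      } else {
        lf <- uniroot(function(v) prop_at_eta1(v) - target, c(lf, hi),
                      tol = 1e-9)$root
      }
    }
    m <- curve_model(k, ly, lmax, lf, ductility = 1,
                     step = step, noise_sd = noise_sd)
    calibrate_ductility(m, target, interval = c(1, 200))
  })
  names(models) <- if ("mouse" %in% names(cohort)) cohort$mouse else
    as.character(seq_len(nrow(cohort)))
  models
}

#' Simulate load-displacement curves for a cohort
#'
#' @param cohort per-mouse table (see [cohort_curve_models()]).
#' @param seed base RNG seed; curve i uses `seed + i`.
#' @param ... passed to [cohort_curve_models()].
#' @return Named list of `ld_curve` objects.
#' @export
simulate_cohort_curves <- function(cohort, seed = 1L, ...) {
  models <- cohort_curve_models(cohort, ...)
  curves <- lapply(seq_along(models), function(i) {
    simulate_curve(models[[i]], seed = seed + i)
  })
  names(curves) <- names(models)
  curves
}
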