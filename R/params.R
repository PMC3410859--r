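#' Phenotype parameter sets
#'
#' The screen measures twelve parameters per mouse: six structural (three by
#' x-ray microradiography, three by micro-CT) and six biomechanical (from
#' destructive 3-point bend testing).
#'
#' @return Character vector of parameter ids.
#' @export
structural_parameters <- function() {
  c("bmc", "bone_length", "cort_th", "bvtv", "tbn", "tbth")
}

#' @rdname structural_parameters
#' @export
biomech_parameters <- function() {
  c("yield_load", "max_load", "fracture_load", "stiffness",
    "prop_de_ml", "prop_de_f")
}

#' @rdname structural_parameters
#' @export
faxitron_parameters <- function() c("bmc", "bone_length", "cort_th")

#' @rdname structural_parameters
#' @export
microct_parameters <- function() c("bvtv", "tbn", "tbth")

#' @rdname structural_parameters
#' @export
all_parameters <- function() c(structural_parameters(), biomech_parameters())

#' Default wild-type reference moments
#'
#' Mean and SD for each of the twelve phenotype parameters in the 16-week-old
#' female C57BL/6 wild-type reference population (n = 77). The four load/
#' stiffness moments and the mean proportion of energy dissipated prior to
#' fracture are the published reference values (stiffness 30.2 +/- 4.1 N/mm;
#' yield 8.9 +/- 0.9 N; maximum 10.7 +/- 0.9 N; fracture 6.4 +/- 1.7 N;
#' 86.2% of energy dissipated prior to failure). The remaining moments are
#' not printed as numbers in the source text and are package placeholders
#' chosen to be biologically plausible for this population (micro-CT
#' placeholder SDs informed by the reported assay coefficients of
#' variation); they carry `placeholder = TRUE` and should be overridden with
#' laboratory-specific reference data when available.
#'
#' @return A data.frame with columns `parameter`, `mean`, `sd`, `unit`,
#'   `placeholder`.
#' @export
wt_parameter_defaults <- function() {
  data.frame(
    parameter = all_parameters(),
    mean = c(
      bmc = 140, bone_length = 17.6, cort_th = 0.23,
      bvtv = 15.5, tbn = 4.5, tbth = 0.049,
      yield_load = 8.9, max_load = 10.7, fracture_load = 6.4,
      stiffness = 30.2, prop_de_ml = 0.32, prop_de_f = 0.862
    ),
    sd = c(
      bmc = 8, bone_length = 0.45, cort_th = 0.02,
      bvtv = 2.9, tbn = 0.8, tbth = 0.0055,
      yield_load = 0.9, max_load = 0.9, fracture_load = 1.7,
      stiffness = 4.1, prop_de_ml = 0.05, prop_de_f = 0.03
    ),
    unit = c(
      "grey level", "mm", "mm", "%", "1/mm", "mm",
      "N", "N", "N", "N/mm", "fraction", "fraction"
    ),
    placeholder = c(
      TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
      FALSE, FALSE, FALSE, FALSE, TRUE, FALSE
    ),
    row.names = NULL
  )
}

#' Default cross-parameter correlation matrix
#'
#' Bone strength correlates with mineral content and cortical geometry but
#' not with trabecular micro-CT measures, so the default imposes a moderate
#' positive correlation (0.5) among BMC, cortical thickness and the three
#' load parameters, and independence elsewhere.
#'
#' @param rho correlation among the correlated block (default 0.5).
#' @return A 12 x 12 correlation matrix over [all_parameters()].
#' @export
default_correlation <- function(rho = 0.5) {
  pars <- all_parameters()
  R <- diag(length(pars))
  dimnames(R) <- list(pars, pars)
  block <- c("bmc", "cort_th", "yield_load", "max_load", "fracture_load")
  R[block, block] <- rho
  diag(R) <- 1
  R
}
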