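#' Functional categories of bone strength
#'
#' Normal bone is strong and flexible with normal mineral content; the
#' three abnormal clusters are weak but flexible with low BMC, weak and
#' brittle with low BMC, and strong but brittle with high BMC.
#'
#' @return Character vector of the four category ids.
#' @export
functional_categories <- function() {
  c("normal_strong_flexible", "weak_flexible_lowBMC",
    "weak_brittle_lowBMC", "strong_brittle_highBMC")
}

#' Classify a strain into a functional category of bone strength
#'
#' Rules, applied to strain-mean SD distances: *weak* iff the maximum-load
#' z-score is below -k, *strong* iff above +k; *brittle* iff the z-score of
#' the proportion of energy dissipated prior to fracture is below -k; the
#' BMC direction is taken from the sign of the BMC z-score. The observed
#' clusters map as (weak, flexible, low BMC), (weak, brittle, low BMC) and
#' (strong, brittle, high BMC); everything else is normal/strong-flexible.
#' Combinations outside the observed clusters (for example weak with high
#' BMC, or strong without brittleness) are not forced into a category: they
#' return normal with `review = TRUE`.
#'
#' @param z_max_load,z_prop_de_f,z_bmc strain-mean SD distances.
#' @param k SD threshold (default 2.0).
#' @return Data.frame `category`, `weak`, `strong`, `brittle`, `bmc_low`,
#'   `review` (vectorised over the inputs).
#' @export
classify_strain <- function(z_max_load, z_prop_de_f, z_bmc, k = 2.0) {
  stopifnot(length(z_max_load) == length(z_prop_de_f),
            length(z_max_load) == length(z_bmc))
  if (any(!is.finite(c(z_max_load, z_prop_de_f, z_bmc))))
    stopf("classification requires finite z-scores")
  weak <- z_max_load < -k
  strong <- z_max_load > k
  brittle <- z_prop_de_f < -k
  bmc_low <- z_bmc < 0
  category <- rep("normal_strong_flexible", length(z_max_load))
  review <- rep(FALSE, length(z_max_load))
  wf <- weak & !brittle & bmc_low
  wb <- weak & brittle & bmc_low
  sb <- strong & brittle & !bmc_low
  category[wf] <- "weak_flexible_lowBMC"
  category[wb] <- "weak_brittle_lowBMC"
  category[sb] <- "strong_brittle_highBMC"
  # abnormal strength/ductility patterns outside the observed clusters
  odd <- (weak & !bmc_low) | (strong & bmc_low) | (strong & !brittle) |
    (brittle & !weak & !strong)
  review[odd & !(wf | wb | sb)] <- TRUE
  data.frame(category = category, weak = weak, strong = strong,
             brittle = brittle, bmc_low = bmc_low, review = review,
             stringsAsFactors = FALSE)
}
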