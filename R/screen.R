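#' Build the biomechanical-testing shortlist
#'
#' Union of the structural univariate outliers, the Mahalanobis outliers
#' and the strains carried forward only because the upstream primary screen
#' annotated them.
#'
#' @param structural_flags,mahalanobis_flags named logical vectors over the
#'   strain universe.
#' @param primary_annotations named character vector over the same universe
#'   (`"none"`, `"minor"`, `"major"`).
#' @return List `shortlist` (character), `n`, `n_structural`,
#'   `n_mahalanobis_only`, `n_primary_only`.
#' @export
build_shortlist <- function(structural_flags, mahalanobis_flags,
                            primary_annotations) {
  strains <- names(structural_flags)
  if (!identical(strains, names(mahalanobis_flags)) ||
      !identical(strains, names(primary_annotations)))
    stopf("flag vectors must cover the same strain universe in order")
  primary <- primary_annotations != "none"
  short <- structural_flags | mahalanobis_flags | primary
  list(shortlist = strains[short],
       n = sum(short),
       n_structural = sum(structural_flags),
       n_mahalanobis_only = sum(mahalanobis_flags & !structural_flags),
       n_primary_only = sum(primary & !structural_flags & !mahalanobis_flags))
}

#' Biomechanical screen over the six strength parameters
#'
#' Flags a strain when any of the six biomechanical parameters has a
#' strain-mean SD distance of absolute value greater than `k`.
#'
#' @param summaries strain summary table with `z_<param>` columns for
#'   [biomech_parameters()].
#' @param strains subset of strains to screen (default all).
#' @param k SD threshold (default 2.0).
#' @return Data.frame `strain`, `flagged`, `n_outlier_params`, `incomplete`.
#' @export
biomech_screen <- function(summaries, strains = summaries$strain, k = 2.0) {
  sub <- summaries[summaries$strain %in% strains, , drop = FALSE]
  univariate_screen(sub, biomech_parameters(), k = k)
}

#' Call major skeletal phenotypes
#'
#' A strain has a major phenotype when it carries a biomechanical flag AND
#' corroborating structural or statistical evidence. A biomechanically
#' flagged strain whose only other evidence is a minor primary-screen
#' annotation (no structural flag, no Mahalanobis flag) is demoted: its
#' abnormality is not corroborated by any quantitative imaging measure.
#'
#' @param screen_df data.frame with logical columns `structural_outlier`,
#'   `mahalanobis_outlier`, `biomech_outlier` and character column
#'   `primary` over the strains.
#' @return Logical vector `major_phenotype`.
#' @export
call_major_phenotypes <- function(screen_df) {
  corroborated <- screen_df$structural_outlier |
    screen_df$mahalanobis_outlier |
    screen_df$primary == "major"
  screen_df$biomech_outlier & corroborated
}

#' Run the staged screen over a strain summary table
#'
#' Executes the full algorithm on a per-strain summary: univariate
#' structural screen at `k_struct` SD; Mahalanobis outlier calling at level
#' `alpha` (from a recorded `mahal_d2` column if present, otherwise
#' computed by [mve_estimate()] on the strain-mean structural z-scores);
#' shortlist construction with the primary-screen annotations; biomechanical
#' screen at `k_biomech` SD over the shortlist; major-phenotype calling with
#' demotion of uncorroborated primary-minor strains; functional
#' classification of the majors; and single-biomech-outlier detection among
#' the non-shortlisted strains.
#'
#' @param summaries strain summary table with `z_<param>` columns for all
#'   twelve parameters, and optionally `mahal_d2`, `primary`, `n_mice`.
#' @param k_struct,k_biomech SD thresholds (default 2.0).
#' @param alpha Mahalanobis flagging level (default 0.025).
#' @param mve_seed,n_subsets passed to [mve_estimate()] when distances must
#'   be computed.
#' @return Object of class `screen_result`: list with `result` (per-strain
#'   data.frame of stage flags, category, review flag), `counts` (named
#'   gate counts), `shortlist`, `major_strains`, `thresholds`.
#' @export
screen_strain_table <- function(summaries, k_struct = 2.0, k_biomech = 2.0,
                                alpha = 0.025, mve_seed = 1L,
                                n_subsets = 5000) {
  strains <- summaries$strain
  struct <- univariate_screen(summaries, structural_parameters(), k = k_struct)
  structural_flags <- setNames(struct$flagged, strains)

  p <- length(structural_parameters())
  if ("mahal_d2" %in% names(summaries)) {
    d2 <- summaries$mahal_d2
  } else {
    Z <- as.matrix(summaries[paste0("z_", structural_parameters())])
    est <- mve_estimate(Z, n_subsets = n_subsets, seed = mve_seed)
    d2 <- robust_mahalanobis(Z, est, alpha = alpha)$d2
  }
  mahal_flags <- setNames(d2 > chi2_cutoff(p, alpha), strains)

  primary <- if ("primary" %in% names(summaries)) {
    setNames(as.character(summaries$primary), strains)
  } else {
    setNames(rep("none", length(strains)), strains)
  }

  short <- build_shortlist(structural_flags, mahal_flags, primary)
  bio_all <- univariate_screen(summaries, biomech_parameters(), k = k_biomech)
  biomech_flags <- setNames(bio_all$flagged, strains)
  in_short <- strains %in% short$shortlist

  df <- data.frame(
    strain = strains,
    structural_outlier = structural_flags,
    mahal_d2 = d2,
    mahalanobis_outlier = mahal_flags,
    primary = primary,
    shortlisted = in_short,
    biomech_outlier = biomech_flags & in_short,
    n_biomech_outlier_params = bio_all$n_outlier_params,
    stringsAsFactors = FALSE, row.names = NULL
  )
  df$major_phenotype <- call_major_phenotypes(df)

  cls <- classify_strain(summaries$z_max_load, summaries$z_prop_de_f,
                         summaries$z_bmc, k = k_biomech)
  df$category <- ifelse(df$major_phenotype, cls$category,
                        "normal_strong_flexible")
  df$review <- df$major_phenotype & cls$review
  single_extra <- !in_short & biomech_flags
  df$single_biomech_only <- single_extra

  counts <- c(
    structural = sum(df$structural_outlier),
    mahalanobis = sum(df$mahalanobis_outlier),
    mahalanobis_only = short$n_mahalanobis_only,
    primary_only = short$n_primary_only,
    shortlist = short$n,
    biomech_in_shortlist = sum(df$biomech_outlier),
    additional_single_biomech = sum(single_extra),
    major = sum(df$major_phenotype)
  )
  structure(
    list(result = df, counts = counts, shortlist = short$shortlist,
         major_strains = df$strain[df$major_phenotype],
         thresholds = list(k_struct = k_struct, k_biomech = k_biomech,
                           alpha = alpha)),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Skeletal phenotype screen\n")
  cat(sprintf("  thresholds: %.1f SD structural, %.1f SD biomechanical, alpha %.3g\n",
              x$thresholds$k_struct, x$thresholds$k_biomech,
              x$thresholds$alpha))
  for (nm in names(x$counts))
    cat(sprintf("  %-26s %d\n", nm, x$counts[[nm]]))
  cat("  major strains:", paste(x$major_strains, collapse = ", "), "\n")
  invisible(x)
}

#' Run the screen end-to-end from per-mouse tables
#'
#' Builds reference ranges from the wild-type per-mouse table, summarises
#' the knockout table to strain level, then applies
#' [screen_strain_table()]. Mahalanobis distances are computed by the MVE
#' estimator fit, per the default mode, on the knockout strain-mean
#' structural z-scores (robustness tolerates the outlying strains
#' themselves); `mode = "wt_anchored"` instead fits location and scatter on
#' the wild-type mice and measures strain means against them.
#'
#' @param wt_table wild-type per-mouse table.
#' @param ko_table knockout per-mouse table with a `strain` column.
#' @param primary_annotations optional named character vector
#'   (strain -> `"none"`/`"minor"`/`"major"`).
#' @param mode `"strain_means"` (default) or `"wt_anchored"`.
#' @param ... thresholds passed to [screen_strain_table()].
#' @return A `screen_result`; the strain summary table is attached as
#'   `$summaries`.
#' @export
run_screen <- function(wt_table, ko_table, primary_annotations = NULL,
                       mode = c("strain_means", "wt_anchored"), ...) {
  mode <- match.arg(mode)
  ranges <- build_reference_ranges(wt_table)
  summaries <- strain_summaries(ko_table, ranges)
  if (!is.null(primary_annotations)) {
    summaries$primary <- unname(primary_annotations[summaries$strain])
    summaries$primary[is.na(summaries$primary)] <- "none"
  }
  if (mode == "wt_anchored") {
    zcols <- paste0("z_", structural_parameters())
    Zwt <- scale(as.matrix(wt_table[structural_parameters()]),
                 center = vapply(ranges[structural_parameters()],
                                 `[[`, numeric(1), "mean"),
                 scale = vapply(ranges[structural_parameters()],
                                `[[`, numeric(1), "sd"))
    est <- mve_estimate(Zwt, n_subsets = 5000, seed = 1L)
    Z <- as.matrix(summaries[zcols])
    summaries$mahal_d2 <- robust_mahalanobis(Z, est)$d2
  }
  res <- screen_strain_table(summaries, ...)
  res$summaries <- summaries
  res
}
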