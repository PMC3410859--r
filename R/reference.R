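#' Build a wild-type reference range for one parameter
#'
#' Sample mean and SD (n-1 denominator) of the wild-type values, with the
#' symmetric bands at 1, 2 and 3 SD used by the reference-range screen.
#'
#' @param wt_values numeric vector of wild-type measurements (>= 2 finite).
#' @param parameter parameter id.
#' @return Object of class `reference_range`: `parameter`, `mean`, `sd`,
#'   `n`, `bands` (2-column matrix, rows `1SD`/`2SD`/`3SD`).
#' @export
build_reference_range <- function(wt_values, parameter = "parameter") {
  v <- wt_values[is.finite(wt_values)]
  if (length(v) < 2) stopf("need >= 2 finite wild-type values for '%s'",
                           parameter)
  m <- mean(v)
  s <- sd(v)
  if (s == 0) stopf("wild-type values for '%s' are constant (SD 0)", parameter)
  bands <- cbind(lower = m - (1:3) * s, upper = m + (1:3) * s)
  rownames(bands) <- paste0(1:3, "SD")
  structure(list(parameter = parameter, mean = m, sd = s, n = length(v),
                 bands = bands),
            class = "reference_range")
}

#' Reference ranges for every parameter of a wild-type table
#'
#' @param wt_table per-mouse wild-type table.
#' @param parameters parameter columns to use (default [all_parameters()]
#'   intersected with the table).
#' @return Named list of [build_reference_range()] objects.
#' @export
build_reference_ranges <- function(wt_table,
                                   parameters = intersect(all_parameters(),
                                                          names(wt_table))) {
  setNames(lapply(parameters, function(p)
    build_reference_range(wt_table[[p]], p)), parameters)
}

#' SD distance (z-score) of a value from a reference range
#'
#' @param value observed value(s).
#' @param range a [build_reference_range()] object.
#' @return `(value - mean) / SD`.
#' @export
sd_distance <- function(value, range) {
  stopifnot(inherits(range, "reference_range"))
  (value - range$mean) / range$sd
}

#' Summarise a knockout cohort to strain level
#'
#' Strain means for each parameter and their SD distances from the
#' wild-type reference mean. Screening operates on these strain-mean
#' z-scores.
#'
#' @param mouse_table per-mouse table with a `strain` column and parameter
#'   columns.
#' @param ranges named list of reference ranges (see
#'   [build_reference_ranges()]).
#' @return Data.frame with `strain`, `n_mice`, one `<param>` mean column
#'   and one `z_<param>` column per parameter.
#' @export
strain_summaries <- function(mouse_table, ranges) {
  params <- names(ranges)
  strains <- unique(mouse_table$strain)
  rows <- lapply(strains, function(s) {
    sub <- mouse_table[mouse_table$strain == s, , drop = FALSE]
    means <- vapply(params, function(p) mean(sub[[p]]), numeric(1))
    zs <- vapply(params, function(p) sd_distance(means[[p]], ranges[[p]]),
                 numeric(1))
    out <- data.frame(strain = s, n_mice = nrow(sub))
    out[params] <- as.list(means)
    out[paste0("z_", params)] <- as.list(zs)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Univariate reference-range screen
#'
#' A strain is flagged when any parameter in the set has a strain-mean SD
#' distance of absolute value greater than `k` (two-sided: abnormally high
#' and abnormally low phenotypes both count). Strains with missing values
#' in the screened parameters are reported as incomplete rather than
#' silently passed.
#'
#' @param summaries strain summary table (see [strain_summaries()]) with
#'   `z_<param>` columns.
#' @param parameters parameter ids to screen.
#' @param k SD threshold (default 2.0).
#' @return Data.frame `strain`, `flagged`, `n_outlier_params`, `incomplete`.
#' @export
univariate_screen <- function(summaries, parameters = structural_parameters(),
                              k = 2.0) {
  if (k <= 0) stopf("threshold k must be > 0")
  zcols <- paste0("z_", parameters)
  miss <- setdiff(zcols, names(summaries))
  if (length(miss)) stopf("summary table lacks columns: %s",
                          paste(miss, collapse = ", "))
  Z <- as.matrix(summaries[zcols])
  incomplete <- apply(Z, 1, function(r) any(!is.finite(r)))
  n_out <- rowSums(abs(Z) > k, na.rm = TRUE)
  data.frame(strain = summaries$strain,
             flagged = n_out > 0,
             n_outlier_params = n_out,
             incomplete = incomplete,
             stringsAsFactors = FALSE)
}

#' Diagnostic accuracy of a flagging method against known truth
#'
#' Standard 2x2 ratios: sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' positive and negative predictive values. Undefined ratios (zero
#' denominator) are returned as NA.
#'
#' @param flags named logical vector (or character vector of flagged
#'   strains).
#' @param truth named logical vector over the same strain universe (or
#'   character vector of true-positive strains).
#' @param universe strain universe when `flags`/`truth` are character.
#' @return List `table` (2x2 counts), `sensitivity`, `specificity`, `ppv`,
#'   `npv`.
#' @export
diagnostic_accuracy <- function(flags, truth, universe = NULL) {
  if (is.character(flags) || is.character(truth)) {
    if (is.null(universe)) stopf("universe required for character input")
    flags <- setNames(universe %in% flags, universe)
    truth <- setNames(universe %in% truth, universe)
  }
  if (length(truth) == 0) stopf("empty truth set")
  if (!identical(names(flags), names(truth)))
    truth <- truth[names(flags)]
  if (any(is.na(truth))) stopf("flags and truth cover different strains")
  tp <- sum(flags & truth); fp <- sum(flags & !truth)
  fn <- sum(!flags & truth); tn <- sum(!flags & !truth)
  ratio <- function(a, b) if (b > 0) a / b else NA_real_
  list(table = matrix(c(tp, fp, fn, tn), 2, 2,
                      dimnames = list(flag = c("yes", "no"),
                                      truth = c("yes", "no"))),
       sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       ppv = ratio(tp, tp + fp),
       npv = ratio(tn, tn + fn))
}

#' Pearson correlations between parameter pairs
#'
#' @param table per-mouse or per-strain table.
#' @param pairs 2-column character matrix (or data.frame) of parameter
#'   pairs; default all pairs of the numeric columns.
#' @return Data.frame `x`, `y`, `r`, `p_value`, `n`.
#' @export
pearson_correlations <- function(table, pairs = NULL) {
  if (is.null(pairs)) {
    num <- names(table)[vapply(table, is.numeric, logical(1))]
    pairs <- t(combn(num, 2))
  }
  pairs <- as.matrix(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- table[[pairs[i, 1]]]
    y <- table[[pairs[i, 2]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) stopf("need >= 3 paired observations for %s vs %s",
                           pairs[i, 1], pairs[i, 2])
    if (var(x[ok]) == 0 || var(y[ok]) == 0)
      stopf("zero variance in %s or %s", pairs[i, 1], pairs[i, 2])
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    data.frame(x = pairs[i, 1], y = pairs[i, 2],
               r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
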