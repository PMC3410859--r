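#' Read and write cohort and strain tables as delimited text
#'
#' Tables are tab-separated with a header row. `load_cohort_table()`
#' validates that the required columns are present and that every parameter
#' column is numeric, reporting offending rows by number.
#'
#' @param path file path.
#' @param required columns that must be present (default: `strain` plus any
#'   parameter or z-score columns found).
#' @return A data.frame.
#' @export
load_cohort_table <- function(path, required = "strain") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stopf("table %s lacks required columns: %s", path,
          paste(miss, collapse = ", "))
  num_cols <- intersect(c(all_parameters(), paste0("z_", all_parameters()),
                          "mahal_d2"), names(tab))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]) & tab[[col]] != "")
    if (length(bad))
      stopf("column '%s' has non-numeric values at rows: %s", col,
            paste(head(bad, 5), collapse = ", "))
    tab[[col]] <- v
  }
  tab
}

#' @rdname load_cohort_table
#' @param table data.frame to write.
#' @export
write_cohort_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a screen report
#'
#' Emits the per-strain result table, the gate counts, and the data behind
#' the classification plot (proportion of energy dissipated prior to
#' fracture, angular scale, versus maximum load) as delimited text files
#' under `dir`.
#'
#' @param screen a `screen_result` from [screen_strain_table()] or
#'   [run_screen()].
#' @param dir output directory (created if absent).
#' @param summaries optional strain summary table supplying the z-scores
#'   for the plot data (taken from `screen$summaries` when present).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(screen, dir, summaries = screen$summaries) {
  stopifnot(inherits(screen, "screen_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    result = file.path(dir, "screen_result.tsv"),
    counts = file.path(dir, "gate_counts.tsv"),
    plot = file.path(dir, "classification_plot.tsv")
  )
  write_cohort_table(screen$result, paths["result"])
  write_cohort_table(
    data.frame(gate = names(screen$counts), count = unname(screen$counts)),
    paths["counts"])
  if (!is.null(summaries) &&
      all(c("z_max_load", "z_prop_de_f") %in% names(summaries))) {
    plot_df <- data.frame(
      strain = summaries$strain,
      z_max_load = summaries$z_max_load,
      z_prop_de_f = summaries$z_prop_de_f,
      category = screen$result$category[match(summaries$strain,
                                              screen$result$strain)]
    )
    if ("prop_de_f" %in% names(summaries))
      plot_df$ang_prop_de_f <- angular_transform(
        pmin(pmax(summaries$prop_de_f, 0), 1))
    if ("max_load" %in% names(summaries))
      plot_df$max_load <- summaries$max_load
    write_cohort_table(plot_df, paths["plot"])
  } else {
    paths <- paths[c("result", "counts")]
  }
  invisible(paths)
}
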