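test_that("shortlist is the union of structural, Mahalanobis and primary evidence", {
  u <- c("a", "b", "c", "d")
  s <- setNames(c(TRUE, FALSE, FALSE, FALSE), u)
  m <- setNames(c(FALSE, TRUE, FALSE, FALSE), u)
  p <- setNames(c("none", "none", "minor", "none"), u)
  r <- build_shortlist(s, m, p)
  expect_setequal(r$shortlist, c("a", "b", "c"))
  expect_equal(r$n, 3)
  expect_equal(r$n_mahalanobis_only, 1)
  expect_equal(r$n_primary_only, 1)
  empty <- build_shortlist(setNames(c(FALSE, FALSE), c("x", "y")),
                           setNames(c(FALSE, FALSE), c("x", "y")),
                           setNames(c("none", "none"), c("x", "y")))
  expect_length(empty$shortlist, 0)
  expect_error(build_shortlist(s, m[c(2, 1, 3, 4)], p), "same strain universe")
})

test_that("functional classification follows the published cluster patterns", {
  expect_equal(classify_strain(-3, 0.2, -2.5)$category, "weak_flexible_lowBMC")
  expect_equal(classify_strain(-3, -3, -2.5)$category, "weak_brittle_lowBMC")
  expect_equal(classify_strain(3, -3, 2.5)$category, "strong_brittle_highBMC")
  expect_equal(classify_strain(0.3, -0.1, 1.0)$category,
               "normal_strong_flexible")
  # combinations outside the observed clusters are flagged for review
  odd <- classify_strain(3, -3, -2.5)   # strong + brittle + low BMC
  expect_equal(odd$category, "normal_strong_flexible")
  expect_true(odd$review)
  odd2 <- classify_strain(0, -3, 1)     # brittle alone
  expect_true(odd2$review)
  expect_error(classify_strain(NA, 1, 1), "finite")
})

test_that("every strain receives exactly one category", {
  set.seed(31)
  z <- matrix(rnorm(300 * 3, sd = 2), 300, 3)
  cls <- classify_strain(z[, 1], z[, 2], z[, 3])
  expect_equal(nrow(cls), 300)
  expect_true(all(cls$category %in% functional_categories()))
})

test_that("major-phenotype calling demotes uncorroborated primary-minor strains", {
  df <- data.frame(
    structural_outlier = c(TRUE, FALSE, FALSE, FALSE),
    mahalanobis_outlier = c(FALSE, TRUE, FALSE, FALSE),
    biomech_outlier = c(TRUE, TRUE, TRUE, TRUE),
    primary = c("none", "minor", "minor", "major")
  )
  expect_equal(call_major_phenotypes(df), c(TRUE, TRUE, FALSE, TRUE))
})

test_that("the screen reproduces its published gate structure on the synthetic table", {
  res <- screen_strain_table(synthetic_strain_table())
  expect_equal(unname(res$counts["structural"]), 19)
  expect_equal(unname(res$counts["mahalanobis"]), 40)
  expect_equal(unname(res$counts["mahalanobis_only"]), 24)
  expect_equal(unname(res$counts["primary_only"]), 8)
  expect_equal(unname(res$counts["shortlist"]), 51)
  expect_equal(unname(res$counts["biomech_in_shortlist"]), 12)
  expect_equal(unname(res$counts["additional_single_biomech"]), 7)
  expect_equal(unname(res$counts["major"]), 10)
  expect_setequal(res$major_strains,
                  c("Asxl1", "Bbx", "Cadm1", "Fam73b", "Prpsap2", "Setdb1",
                    "Slc38a10", "Sparc", "Spns2", "Trim45"))
  cats <- res$result[res$result$major_phenotype, ]
  expect_equal(sort(cats$strain[cats$category == "weak_flexible_lowBMC"]),
               c("Bbx", "Cadm1", "Fam73b"))
  expect_equal(sort(cats$strain[cats$category == "weak_brittle_lowBMC"]),
               c("Prpsap2", "Slc38a10", "Sparc"))
  expect_equal(sort(cats$strain[cats$category == "strong_brittle_highBMC"]),
               c("Asxl1", "Setdb1", "Spns2", "Trim45"))
})

test_that("raising thresholds never increases any gate count", {
  tab <- synthetic_strain_table()
  base <- screen_strain_table(tab)
  stricter <- screen_strain_table(tab, k_struct = 3, k_biomech = 2,
                                  alpha = 0.003)
  for (gate in c("structural", "mahalanobis", "shortlist",
                 "biomech_in_shortlist", "major"))
    expect_lte(stricter$counts[[gate]], base$counts[[gate]])
  # the published direction: 19 -> 9 structural, 40 -> 21 Mahalanobis,
  # and 8 major strains retained including Trim45 and Sparc
  expect_equal(unname(stricter$counts["structural"]), 9)
  expect_equal(unname(stricter$counts["mahalanobis"]), 21)
  expect_equal(unname(stricter$counts["major"]), 8)
  expect_true(all(c("Trim45", "Sparc") %in% stricter$major_strains))
})

test_that("Venn overlaps are internally consistent on the synthetic table", {
  tab <- synthetic_strain_table()
  res <- screen_strain_table(tab)
  df <- res$result
  a <- df$structural_outlier
  m <- df$mahalanobis_outlier
  p <- df$primary != "none"
  expect_equal(sum(a | m | p), unname(res$counts["shortlist"]))
  expect_equal(sum(m & !a), unname(res$counts["mahalanobis_only"]))
  expect_equal(sum(p), 17)
  expect_equal(sum(p & (a | m)), 9)
  # incorrectly targeted strains are carried, unflagged
  it <- tab$strain[tab$incorrectly_targeted]
  expect_setequal(it, c("Psmb2", "5031439G07Rik"))
  expect_false(any(df$major_phenotype[df$strain %in% it]))
})

test_that("the full pipeline recovers planted phenotypes and stays quiet on wild type", {
  spec <- cohort_spec(seed = 7)
  wt <- simulate_wt_cohort(spec)
  planted <- setNames(
    as.list(rep(c("weak_flexible_lowBMC", "weak_brittle_lowBMC",
                  "strong_brittle_highBMC"), each = 4)),
    as.character(1:12))
  ko <- simulate_ko_cohort(spec, planted = planted, magnitude = 4, seed = 99)
  res <- run_screen(wt, ko$mice)
  got <- res$result[match(ko$truth$strain, res$result$strain), ]
  planted_rows <- ko$truth$category != "normal"
  expect_true(all(got$major_phenotype[planted_rows]))
  expect_equal(got$category[planted_rows], ko$truth$category[planted_rows])
  # a screen over pure wild-type replicate strains calls ~0 majors
  ko0 <- simulate_ko_cohort(cohort_spec(seed = 3, n_strains = 60), seed = 51)
  res0 <- run_screen(wt, ko0$mice)
  expect_lte(unname(res0$counts["major"]), 2)
})

test_that("the wild-type-anchored Mahalanobis mode runs and flags planted strains", {
  spec <- cohort_spec(seed = 17, n_strains = 30)
  wt <- simulate_wt_cohort(spec)
  ko <- simulate_ko_cohort(spec,
                           planted = list(`1` = "weak_brittle_lowBMC"),
                           magnitude = 5, seed = 23)
  res <- run_screen(wt, ko$mice, mode = "wt_anchored")
  expect_true(res$result$mahalanobis_outlier[res$result$strain == "KO001"])
})

test_that("cohort tables round-trip through delimited text with validation", {
  tab <- synthetic_strain_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_table(tab, path)
  back <- load_cohort_table(path, required = c("strain", "mahal_d2"))
  expect_equal(back$strain, tab$strain)
  expect_equal(back$z_max_load, tab$z_max_load, tolerance = 1e-9)
  # malformed numeric cell is reported with its row number
  bad <- readLines(path)
  fields <- strsplit(bad[4], "\t")[[1]]
  fields[6] <- "not-a-number"
  bad[4] <- paste(fields, collapse = "\t")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(bad, path2)
  expect_error(load_cohort_table(path2), "rows: 3")
  expect_error(load_cohort_table("no/such/file.tsv"), "no such file")
  expect_error(load_cohort_table(path, required = "nope"), "required columns")
})

test_that("screen reports are written as delimited text", {
  res <- screen_strain_table(synthetic_strain_table())
  res$summaries <- synthetic_strain_table()
  dir <- withr::local_tempdir()
  paths <- write_report(res, dir)
  expect_true(all(file.exists(paths)))
  counts <- read.delim(paths["counts"])
  expect_equal(counts$count[counts$gate == "major"], 10)
  plot_df <- read.delim(paths["plot"])
  expect_equal(nrow(plot_df), 100)
})
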