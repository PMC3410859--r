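test_that("elastic region spans an exactly linear limb with R-squared 1", {
  cv <- triangle_curve(k = 30, lmax = 9)
  reg <- find_elastic_region(cv)
  expect_equal(reg$r_squared, 1, tolerance = 1e-9)
  # candidate band is 10-80% of max load; the window should cover it
  l <- cv$load_N
  band <- which(l >= 0.1 * 9 & l <= 0.8 * 9 & seq_along(l) <= which.max(l))
  expect_lte(reg$start, min(band) + 1)
  expect_gte(reg$end, max(band) - 1)
})

test_that("elastic region of a bilinear curve is confined to the first limb", {
  # slope 30 up to 6 N, then slope 5; exhaustive lm() window search oracle
  d1 <- seq(0, 0.2, by = 0.004)
  d2 <- seq(0.204, 0.6, by = 0.004)
  d <- c(d1, d2)
  l <- c(30 * d1, 6 + 5 * (d2 - 0.2))
  cv <- load_displacement_curve(c(d, 0.604, 0.608), c(l, 0.1, 0))
  reg <- find_elastic_region(cv, min_span = 10)
  kink <- length(d1)
  expect_lte(reg$end, kink)
  fit <- fit_stiffness(cv, reg)
  expect_equal(fit$stiffness, 30, tolerance = 1e-6)
  # oracle: no window of >= 10 samples crossing the kink has higher R^2
  lmax <- max(l)
  band <- which(l >= 0.1 * lmax & l <= 0.8 * lmax &
                  seq_along(l) <= which.max(l))
  best <- -Inf
  for (s in band) for (e in band[band >= s + 9]) {
    r2 <- suppressWarnings(summary(stats::lm(l[s:e] ~ d[s:e]))$r.squared)
    if (r2 > best + 1e-12) best <- r2
  }
  expect_equal(reg$r_squared, best, tolerance = 1e-9)
})

test_that("curves too short for the minimum span are rejected", {
  d <- seq(0, 0.9, by = 0.1)
  cv <- load_displacement_curve(d, c(seq(2, 10, by = 1), 0.3))
  expect_error(find_elastic_region(cv, min_span = 10), "at least 10 samples")
})

test_that("least-squares stiffness is exact on a line and calibrated under noise", {
  cv <- triangle_curve(k = 30, lmax = 9)
  expect_equal(fit_stiffness(cv)$stiffness, 30, tolerance = 1e-12)
  # slope 30.2 + N(0, 0.1) noise over 100 points: closed-form OLS slope SE
  set.seed(1)
  d <- seq(0.01, 1, length.out = 100)
  se <- 0.1 / sqrt(sum((d - mean(d))^2))
  err <- replicate(50, {
    l <- 30.2 * d + rnorm(100, 0, 0.1)
    cv2 <- load_displacement_curve(d, l)
    reg <- list(start = 1, end = 100)
    fit_stiffness(cv2, reg)$stiffness - 30.2
  })
  expect_lt(abs(mean(err)), 4 * se / sqrt(50))
  expect_lt(sd(err), 2 * se)
})

test_that("maximum and fracture loads follow the terminal-drop rule", {
  l <- c(0, 1, 2, 3.5, 5, 7, 9, 10.7, 9.5, 6.4, 0.4)
  d <- seq(0, by = 0.05, length.out = length(l))
  cv <- load_displacement_curve(d, l)
  expect_equal(detect_max(cv)$load, 10.7)
  fr <- detect_fracture(cv)
  expect_equal(fr$load, 6.4)
  expect_false(fr$no_drop)
  # strictly increasing record: fracture = last load, flagged
  cv2 <- load_displacement_curve(seq(0, 1, length.out = 12),
                                 seq(1, 12))
  fr2 <- detect_fracture(cv2)
  expect_equal(fr2$load, 12)
  expect_true(fr2$no_drop)
})

test_that("yield detection flags curves with no plastic phase", {
  cv <- triangle_curve()
  y <- detect_yield(cv, fit_stiffness(cv))
  expect_true(y$at_max)
  expect_equal(y$load, max(cv$load_N))
})

test_that("a secant fraction of 1.0 yields immediately after the region start", {
  # concave curve: every sample beyond the elastic window sits below the line
  m <- curve_model(30, 6, 10, 5, ductility = 3)
  cv <- simulate_curve(m)
  fit <- fit_stiffness(cv)
  y <- detect_yield(cv, fit, fraction = 1.0, refine = FALSE, smooth = 0)
  d_y_idx <- max(which(cv$displacement_mm <= 6 / 30 + 1e-12))
  expect_lte(y$index, d_y_idx + 1)
})

test_that("work energy matches half base times height on a triangle", {
  d <- seq(0, 0.3, length.out = 31)
  cv <- load_displacement_curve(d, 30 * d)
  expect_equal(work_energy(cv, length(d)), 0.5 * 0.3 * 9, tolerance = 1e-12)
  # appending a 10 N plateau over 0.2 mm adds 2.0 N.mm
  d2 <- c(d, seq(0.31, 0.5, length.out = 20))
  l2 <- c(30 * d, rep(10, 20))
  cv2 <- load_displacement_curve(d2, l2)
  add <- work_energy(cv2, length(d2)) - work_energy(cv2, length(d))
  expect_equal(add, 0.5 * (9 + 10) * 0.01 + 10 * 0.19, tolerance = 1e-12)
})

test_that("elastic stored energy is the closed-form triangle area", {
  expect_equal(elastic_stored_energy(10, 30), 10^2 / 60)
  expect_equal(elastic_stored_energy(0, 12.3), 0)
  expect_equal(elastic_stored_energy(10.7, 30.2), 1.896, tolerance = 1e-3)
  expect_error(elastic_stored_energy(10, 0), "stiffness")
  # equals numeric integration of the unloading line to 1e-6
  for (L in c(3, 6.4, 10.7)) for (k in c(22, 30.2)) {
    num <- numeric_area(function(x) k * x, 0, L / k)
    expect_equal(elastic_stored_energy(L, k), num, tolerance = 1e-6)
  }
})

test_that("dissipated energy partitions work and clips noise excess", {
  r <- dissipated_energy(2.0, 0.5)
  expect_equal(r$de, 1.5)
  expect_equal(r$proportion, 0.75)
  expect_false(r$clipped)
  r2 <- dissipated_energy(1.2, 1.2)
  expect_equal(r2$de, 0)
  expect_equal(r2$proportion, 0)
  expect_warning(r3 <- dissipated_energy(1.0, 1.01), "clipped")
  expect_equal(r3$de, 0)
  expect_true(r3$clipped)
  expect_error(dissipated_energy(0, 0), "undefined")
})

test_that("angular transform is arcsin-square-root in radians or degrees", {
  expect_equal(angular_transform(0), 0)
  expect_equal(angular_transform(1), pi / 2)
  expect_equal(angular_transform(0.5), pi / 4)
  expect_equal(angular_transform(0.862), asin(sqrt(0.862)))
  expect_equal(angular_transform(0.862, degrees = TRUE),
               asin(sqrt(0.862)) * 180 / pi)
  expect_error(angular_transform(1.2), "\\[0,1\\]")
})

test_that("noise-free round trip recovers the model parameters within 1%", {
  for (eta in c(1, 1.3, 2)) {
    m <- curve_model(30.2, 8.9, 10.7, 6.4, ductility = eta)
    pr <- analyze_curve(simulate_curve(m))
    expect_equal(pr$stiffness, 30.2, tolerance = 1e-6)
    expect_equal(pr$max_load, 10.7, tolerance = 0.01)
    expect_equal(pr$fracture_load, 6.4, tolerance = 0.01)
    expect_lt(abs(pr$yield_load - 8.9) / 8.9, 0.01)
  }
  # the calibrated wild-type geometry also round-trips the proportion
  pr <- analyze_curve(simulate_curve(wt_model()))
  expect_equal(pr$prop_de_f, 0.862, tolerance = 0.005)
})

test_that("energy conservation holds exactly at both endpoints", {
  set.seed(42)
  for (i in 1:10) {
    m <- curve_model(runif(1, 20, 40), runif(1, 6, 9), runif(1, 9.5, 12),
                     runif(1, 4, 8), ductility = runif(1, 1, 3))
    pr <- analyze_curve(simulate_curve(m))
    expect_equal(pr$de_ml + pr$ese_ml, pr$work_ml, tolerance = 1e-9)
    expect_equal(pr$de_f + pr$ese_f, pr$work_f, tolerance = 1e-9)
    expect_lte(pr$yield_load, pr$max_load + 1e-9)
    expect_lte(pr$fracture_load, pr$max_load + 1e-9)
    expect_gte(min(pr$work_ml, pr$work_f, pr$ese_ml, pr$ese_f,
                   pr$de_ml, pr$de_f), 0)
    expect_true(pr$prop_de_ml >= 0 && pr$prop_de_ml <= 1)
    expect_true(pr$prop_de_f >= 0 && pr$prop_de_f <= 1)
  }
})

test_that("increasing generator ductility strictly increases recovered dissipation", {
  props <- vapply(c(1, 1.5, 2, 3), function(eta) {
    analyze_curve(simulate_curve(
      curve_model(30.2, 8.9, 10.7, 6.4, ductility = eta)))$prop_de_f
  }, numeric(1))
  expect_true(all(diff(props) > 0))
})

test_that("stage failures name the failing stage", {
  d <- seq(0, 1.1, by = 0.1)
  cv <- load_displacement_curve(d, c(seq(2, 20, length.out = 11), 0.3))
  expect_error(analyze_curve(cv, config = list(min_span = 50)),
               "elastic_region")
})

test_that("batch analysis preserves order and ids", {
  curves <- list(a = simulate_curve(wt_model()),
                 b = simulate_curve(curve_model(25, 7, 9, 5, ductility = 1.5)))
  out <- analyze_curves(curves)
  expect_equal(out$id, c("a", "b"))
  expect_equal(out$stiffness[1], 30.2, tolerance = 1e-6)
  expect_equal(out$stiffness[2], 25, tolerance = 1e-6)
})
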