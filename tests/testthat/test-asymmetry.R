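# Relative radii, left-right fits, fan areas, area asymmetries, backside
# metrics and the composed per-slice assessment.

test_that("relative radius normalizes to mean 100 and splits branches", {
  al <- make_aligned(rep(7, 361))
  rr <- relative_radius(al)
  expect_equal(unname(rr$rr), rep(100, 361), tolerance = 1e-12)
  # general contour: normalization identity and the brute-force grid mean
  r <- random_star_radii(base = 120)
  al2 <- make_aligned(r)
  rr2 <- relative_radius(al2)
  expect_equal(mean(rr2$rr), 100, tolerance = 1e-9)
  expect_equal(unname(rr2$rr[181]), 100 * al2$r[181] / mean(al2$r))
  expect_equal(length(rr2$rr_right), 181)
  expect_equal(length(rr2$rr_left), 181)
  expect_identical(rr2$rr_right[1], rr2$rr_left[1])   # shared SP point
})

test_that("ellipse relative radius at the SP matches direct summation", {
  th <- (-180:180) * pi / 180
  r <- (cos(th + pi / 2)^2 / 110^2 + sin(th + pi / 2)^2 / 90^2)^(-1 / 2)
  al <- make_aligned(r)
  rr <- relative_radius(al)
  expect_equal(unname(rr$rr_right[1]), 100 * 90 / mean(r), tolerance = 1e-12)
})

test_that("left-right fit: mirrored, exact-linear and degenerate cases", {
  r <- random_star_radii()
  rr <- relative_radius(make_aligned(r))
  mirrored <- make_profile(rr$rr_right, rr$rr_right)
  fit <- fit_left_right(mirrored, "full")
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 181)
  # pairs on y = 2x + 3 exactly
  x <- 90 + (0:180) / 9
  fit2 <- fit_left_right(make_profile(x, 2 * x + 3), "full")
  expect_equal(fit2$slope, 2, tolerance = 1e-9)
  expect_equal(fit2$intercept, 3, tolerance = 1e-6)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)
  # constant contour: perfect-symmetry convention
  fit3 <- fit_left_right(make_profile(rep(100, 181), rep(100, 181)), "full")
  expect_equal(fit3$slope, 1)
  expect_equal(fit3$r_squared, 1)
  expect_match(torso_warnings(fit3), "convention", all = FALSE)
})

test_that("OLS R-squared equals the squared Pearson correlation", {
  set.seed(42)
  for (i in 1:20) {
    x <- 100 + rnorm(181, sd = 8)
    y <- 0.7 * x + 30 + rnorm(181, sd = runif(1, 0.5, 10))
    fit <- fit_left_right(make_profile(x, y), "full")
    expect_equal(fit$r_squared, stats::cor(x, y)^2, tolerance = 1e-9)
  }
})

test_that("backside fits use separation + 1 paired points", {
  r <- random_star_radii()
  rr <- relative_radius(make_aligned(r))
  fit <- fit_left_right(rr, 70)
  expect_equal(fit$n_points, 71)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  expect_error(fit_left_right(rr, 200), class = "torsometry_validation_error")
})

test_that("fan area matches circle geometry and halves by symmetry", {
  al <- make_aligned(rep(10, 361))
  a_full <- fan_area(al, c(-180, 180))
  expect_lt(abs(a_full - pi * 100) / (pi * 100), 1e-4)
  expect_equal(fan_area(al, c(0, 180)), a_full / 2, tolerance = 1e-12)
  expect_equal(fan_area(al, c(0, 0)), 0)
})

test_that("fan area over the full grid equals the shoelace polygon area", {
  set.seed(11)
  for (i in 1:25) {
    r <- random_star_radii(base = runif(1, 60, 140))
    al <- make_aligned(r)
    # polygon of the grid points (drop the duplicated +180 endpoint)
    th <- (-180:179 - 90) * pi / 180
    poly <- cbind(al$r[1:360] * cos(th + pi / 2), al$r[1:360] * sin(th + pi / 2))
    expect_equal(fan_area(al, c(-180, 180)), abs(shoelace_area_of(poly)),
                 tolerance = 1e-9)
  }
})

test_that("area asymmetry follows its closed form and bounds", {
  expect_equal(area_asymmetry(5, 5), 0)
  expect_equal(area_asymmetry(2, 1), 1 / 3)
  expect_equal(area_asymmetry(1, 0), 1)
  expect_error(area_asymmetry(0, 0), class = "torsometry_validation_error")
  set.seed(3)
  for (i in 1:50) {
    v <- runif(2, 0, 1e4)
    a <- area_asymmetry(v[1], v[2])
    expect_true(a >= 0 && a <= 1)
    if (abs(v[1] - v[2]) > 1e-9) expect_gt(a, 0)
  }
})

test_that("Dist_VB on a circle matches the closed form", {
  R <- 100
  al <- make_aligned(rep(R, 361))
  anchors <- locate_backside_anchors(al, 70)
  vb <- estimate_vb_line(al, sp_offset = 30)
  bm <- backside_metrics(al, anchors, vb)
  offs <- 0:70
  d_expected <- R * cos(offs * pi / 180) - (R - 30)
  expect_equal(bm$dist_vb_right, d_expected, tolerance = 1e-6)
  expect_equal(bm$dist_vb_left, d_expected, tolerance = 1e-6)
  expect_equal(bm$backside_area_asym, 0, tolerance = 1e-12)
})

test_that("a right-side hump raises right-side distances and areas", {
  spec <- preset_spec("thoracic_t8")   # hump at +50 degrees (right)
  g <- generate_contour(spec, "T8")
  s <- analyze_contour(g$contour)
  expect_gt(s$ra, s$la)
  expect_gt(s$backside_area_asym, 0.01)
  hump_ix <- 40:60
  expect_true(all(s$dist_vb_right[hump_ix] > s$dist_vb_left[hump_ix]))
  expect_equal(g$truth$hump_side, "right")
})

test_that("assess_slice on a symmetric slice reports perfect symmetry", {
  g <- generate_contour(preset_spec("healthy"), "T8")
  s <- analyze_contour(g$contour)
  expect_equal(s$r_squared_full, 1, tolerance = 1e-9)
  expect_lt(s$lr_area_asym, 1e-10)
  expect_lt(s$backside_area_asym, 1e-10)
  expect_equal(s$dist_vb_left, s$dist_vb_right, tolerance = 1e-9)
})

test_that("asymmetry parameters are scale-invariant, areas quadratic", {
  g <- generate_contour(preset_spec("thoracic_t8"), "T8")
  s1 <- analyze_contour(g$contour)
  scaled <- raw_contour(unclass(g$contour) * 2.5, check_simple = FALSE)
  s2 <- analyze_contour(scaled, sp_offset = 40 * 2.5)
  expect_equal(s2$lr_area_asym, s1$lr_area_asym, tolerance = 1e-9)
  expect_equal(s2$r_squared_full, s1$r_squared_full, tolerance = 1e-9)
  expect_equal(s2$la / s1$la, 2.5^2, tolerance = 1e-6)
  expect_equal(s2$ra / s1$ra, 2.5^2, tolerance = 1e-6)
})

test_that("random mirror-symmetric contours are scored as symmetric", {
  set.seed(99)
  for (i in 1:8) {
    g <- generate_contour(random_symmetric_spec(), "T8")
    s <- analyze_contour(g$contour)
    expect_equal(s$r_squared_full, 1, tolerance = 1e-9)
    expect_equal(s$slope_full, 1, tolerance = 1e-6)
    expect_lt(s$lr_area_asym, 1e-10)
  }
})
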