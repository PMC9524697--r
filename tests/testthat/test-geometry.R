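# Centroid, polar conversion, SP detection, alignment, resampling,
# backside anchors and the vertebral-body line.

test_that("centroid is the arithmetic mean of the contour points", {
  ct <- make_circle(r = 5, center = c(2, 3), n = 360)
  expect_equal(compute_centroid(ct), c(2, 3), tolerance = 1e-12)
  # direct re-summation oracle on an asymmetric contour
  g <- generate_contour(preset_spec("thoracic_t8"), "T8")
  expect_equal(compute_centroid(g$contour),
               c(sum(g$contour[, 1]), sum(g$contour[, 2])) / nrow(g$contour))
})

test_that("polar conversion: square and circle radii, outside-origin error", {
  sq <- make_square(s = 1, per_side = 16)
  p <- to_polar(sq, origin = c(0, 0))
  r_at <- function(th) p$r[which.min(abs(p$theta - th))]
  expect_equal(r_at(0), 1, tolerance = 1e-12)
  expect_equal(r_at(45), sqrt(2), tolerance = 1e-12)
  expect_equal(r_at(90), 1, tolerance = 1e-12)
  ci <- to_polar(make_circle(r = 7, n = 180))
  expect_equal(ci$r, rep(7, 180), tolerance = 1e-12)
  expect_error(to_polar(sq, origin = c(100, 100)),
               class = "torsometry_geometry_error")
})

test_that("polar round-trips to Cartesian", {
  g <- generate_contour(random_symmetric_spec(), "T5")
  p <- to_polar(g$contour)
  back <- from_polar(p)
  orig <- unclass(g$contour)
  # same point set up to ordering
  key <- function(m) paste(round(m[, 1], 9), round(m[, 2], 9))
  expect_setequal(key(back), key(orig))
})

test_that("non-star contours keep the outer silhouette with a warning", {
  # circle with an inward detour whose angle runs backwards: rays near the
  # detour cross the boundary more than once
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  pts <- cbind(100 * cos(th), 100 * sin(th))
  after <- max(which(th <= 10 * pi / 180))
  detour <- rbind(40 * c(cos(8 * pi / 180), sin(8 * pi / 180)),
                  40 * c(cos(2 * pi / 180), sin(2 * pi / 180)))
  pts <- rbind(pts[1:after, ], detour, pts[(after + 1):180, ])
  ct <- raw_contour(pts, check_simple = FALSE)
  p <- to_polar(ct, origin = c(0, 0))
  expect_match(torso_warnings(p), "star", all = FALSE)
  # the silhouette keeps the outer circle, not the detour radii
  expect_true(all(p$r[p$theta > 0 & p$theta < 10] > 99))
  expect_equal(nrow(p), length(unique(floor(p$theta %% 360))))
})

test_that("SP dip is recovered where it defines the radius minimum", {
  # midline dip on the torso-like superellipse
  spec <- torso_spec(dip_depth = 10, dip_width = 12, dip_angle = 0,
                     n_points = 720)
  sp <- detect_sp(to_polar(generate_contour(spec, "T8")$contour))
  expect_lt(abs(sp$angle + 90), 1)
  expect_false(sp$low_confidence)
  # off-midline dip on a circular base
  spec2 <- torso_spec(base_a = 150, base_b = 150, superellipse_exponent = 2,
                      dip_depth = 10, dip_width = 12, dip_angle = -20,
                      n_points = 720)
  sp2 <- detect_sp(to_polar(generate_contour(spec2, "T8")$contour))
  expect_lt(abs(sp2$angle - (-110)), 1)
})

test_that("a dipless circle yields the posterior midline with low confidence", {
  p <- to_polar(make_circle(r = 80, n = 360))
  sp <- detect_sp(p)
  expect_true(sp$low_confidence)
  expect_lt(abs(sp$angle + 90), 1)
})

test_that("alignment is rotation-equivariant and idempotent", {
  spec <- preset_spec("thoracic_t8")
  g <- generate_contour(spec, "T8")
  base <- to_polar(g$contour)
  sp0 <- detect_sp(base)
  al0 <- resample_angular(align_slice(base, sp0$angle))
  for (phi in c(17, -40, 120)) {
    rot <- phi * pi / 180
    pts <- unclass(g$contour) %*% t(matrix(c(cos(rot), -sin(rot),
                                             sin(rot), cos(rot)), 2, byrow = TRUE))
    ctr <- raw_contour(pts, check_simple = FALSE)
    p <- to_polar(ctr)
    sp <- detect_sp(p, search_sector = c(-150 + phi, -30 + phi))
    al <- resample_angular(align_slice(p, sp$angle))
    d <- (al$rotation_applied - al0$rotation_applied + phi) %% 360
    expect_lt(min(d, 360 - d), 1e-6)
    expect_lt(max(abs(al$r - al0$r)) / al0$mean_radius, 1e-6)
  }
  # re-aligning an already-aligned contour applies (numerically) no rotation
  aligned_pts <- cbind(al0$r * sin(al0$theta * pi / 180),
                       -al0$r * cos(al0$theta * pi / 180))[-361, ]
  p2 <- to_polar(raw_contour(aligned_pts, check_simple = FALSE))
  sp2 <- detect_sp(p2)
  al2 <- align_slice(p2, sp2$angle)
  d2 <- abs(attr(al2, "rotation_applied")) %% 360
  expect_lt(min(d2, 360 - d2), 1)
})

test_that("angular resampling is exact for constants and linear ramps", {
  # constant: a circle at arbitrary sample angles
  set.seed(7)
  th <- sort(runif(200, -180, 180))
  pol <- structure(data.frame(theta = th, r = rep(5, 200)),
                   class = c("polar_contour", "data.frame"),
                   frame = "aligned_offset", rotation_applied = 0)
  out <- resample_angular(pol)
  expect_equal(out$r, rep(5, 361), tolerance = 1e-12)
  expect_equal(out$mean_radius, 5, tolerance = 1e-12)
  # linear ramp r = 100 + theta/10 sampled every 0.5 degree
  th2 <- seq(-180, 179.5, by = 0.5)
  pol2 <- structure(data.frame(theta = th2, r = 100 + th2 / 10),
                    class = c("polar_contour", "data.frame"),
                    frame = "aligned_offset", rotation_applied = 0)
  out2 <- resample_angular(pol2)
  inner <- out2$theta > -180 & out2$theta < 180
  expect_equal(out2$r[inner], 100 + out2$theta[inner] / 10, tolerance = 1e-9)
  # mean radius equals the grid mean by construction
  expect_identical(out2$mean_radius, mean(out2$r))
})

test_that("resampling flags large angular gaps", {
  th <- seq(-180, 179, by = 1)
  keep <- th < 60 | th > 80    # 20-degree gap
  pol <- structure(data.frame(theta = th[keep], r = rep(10, sum(keep))),
                   class = c("polar_contour", "data.frame"),
                   frame = "aligned_offset", rotation_applied = 0)
  out <- resample_angular(pol)
  expect_match(torso_warnings(out), "gap", all = FALSE)
})

test_that("backside anchors sit at the requested separation", {
  al <- make_aligned(rep(100, 361))
  a70 <- locate_backside_anchors(al, 70)
  expect_equal(a70$brsp_angle, 70)
  expect_equal(a70$blsp_angle, -70)
  a90 <- locate_backside_anchors(al, 90)
  expect_equal(c(a90$brsp_angle, a90$blsp_angle), c(90, -90))
  expect_error(locate_backside_anchors(al, 0),
               class = "torsometry_validation_error")
  expect_error(locate_backside_anchors(al, 180),
               class = "torsometry_validation_error")
})

test_that("vertebral-body line construction and containment checks", {
  al <- make_aligned(rep(100, 361))   # circle r = 100, SP at (0, -100)
  vb <- estimate_vb_line(al, sp_offset = 30)
  expect_equal(vb$vb_center, c(0, -70))
  expect_equal(vb$direction, c(1, 0))
  expect_error(estimate_vb_line(al, 0), class = "torsometry_validation_error")
  expect_error(estimate_vb_line(al, -5), class = "torsometry_validation_error")
  # offset beyond the anterior wall falls outside the contour
  expect_error(estimate_vb_line(al, 2.5 * 100),
               class = "torsometry_validation_error")
})
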