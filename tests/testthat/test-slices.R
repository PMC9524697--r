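# Vertebral level interpolation, mesh loading, plane slicing, arm masking.

test_that("level interpolation is exact at landmarks and affine within spans", {
  lv <- interpolate_levels(c(c7 = 170, t8 = 130, l5 = 85))
  expect_equal(nrow(lv), 18)
  expect_equal(as.character(lv$level), vertebral_levels())
  expect_true(all(diff(lv$height) < 0))
  h <- function(l) lv$height[lv$level == l]
  expect_identical(h("C7"), 170)
  expect_identical(h("T8"), 130)
  expect_identical(h("L5"), 85)
  expect_equal(h("T4"), 170 - 4 * (40 / 8))     # = 150
  # unit spacing case: spans of 8 and 9 equal steps
  lv2 <- interpolate_levels(list(c7 = 8, t8 = 0, l5 = -9))
  expect_equal(lv2$height, 8:-9)
})

test_that("non-monotonic landmarks are rejected", {
  expect_error(interpolate_levels(c(c7 = 100, t8 = 110, l5 = 50)),
               class = "torsometry_validation_error")
  expect_error(interpolate_levels(c(c7 = 100, t8 = 50)),
               class = "torsometry_validation_error")
})

test_that("PLY and OBJ round-trip a unit cube", {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  cube <- torso_mesh(v, f)
  ply <- tempfile(fileext = ".ply")
  write_ply(cube, ply)
  m <- load_mesh(ply)
  expect_equal(nrow(m$vertices), 8)
  expect_equal(nrow(m$faces), 12)
  expect_equal(sort(m$vertices[, 3]), sort(v[, 3]))
  # OBJ with polygon faces and v/vt/vn tokens, fan triangulated
  obj <- tempfile(fileext = ".obj")
  writeLines(c(paste("v", v[, 1], v[, 2], v[, 3]),
               "f 1/1 3/2 4/3 2/4",   # one quad -> two triangles
               paste("f", f[3:12, 1], f[3:12, 2], f[3:12, 3])), obj)
  mo <- load_mesh(obj)
  expect_equal(nrow(mo$vertices), 8)
  expect_equal(nrow(mo$faces), 12)
})

test_that("mesh axis conventions are normalized to up=+z, anterior=+y", {
  # a mesh stored y-up, z-anterior: one marker vertex up high, one anterior
  v <- rbind(c(0, 0, 0), c(0, 10, 0), c(0, 0, 5), c(1, 0, 0))
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 2, 4), c(2, 3, 4))
  ply <- tempfile(fileext = ".ply")
  write_ply(torso_mesh(v, f), ply)
  m <- load_mesh(ply, up_axis = "y", anterior_axis = "z")
  expect_equal(m$vertices[2, 3], 10)   # the high-y marker is now high-z
  expect_equal(m$vertices[3, 2], 5)    # the z-anterior marker is now +y
})

test_that("unreadable or degenerate mesh files raise format errors", {
  empty <- tempfile(fileext = ".ply")
  file.create(empty)
  expect_error(load_mesh(empty), class = "torsometry_format_error")
  bad <- tempfile(fileext = ".ply")
  writeLines(c("not", "a", "ply"), bad)
  expect_error(load_mesh(bad), class = "torsometry_format_error")
  expect_error(load_mesh(tempfile(fileext = ".obj")),
               class = "torsometry_format_error")
})

test_that("slicing a cylinder yields its circular cross-section", {
  mesh <- make_cylinder_mesh(radius = 10, zmin = 0, zmax = 20, n_seg = 256)
  ct <- extract_slice(mesh, 10)
  r <- sqrt(rowSums(unclass(ct)^2))
  expect_lt(max(abs(r - 10)) / 10, 0.01)
  # enclosed area within 1% of pi r^2 at 256 segments
  expect_lt(abs(abs(shoelace_area_of(ct)) - pi * 100) / (pi * 100), 0.01)
  # counterclockwise orientation
  expect_gt(shoelace_area_of(ct), 0)
})

test_that("largest closed loop is kept when the plane cuts several bodies", {
  big <- make_cylinder_mesh(radius = 100, zmin = 0, zmax = 20)
  small <- make_cylinder_mesh(radius = 20, zmin = 0, zmax = 20,
                              center = c(200, 0))
  for (mesh in list(merge_meshes(big, small), merge_meshes(small, big))) {
    ct <- extract_slice(mesh, 10)
    r <- sqrt(rowSums(unclass(ct)^2))
    expect_lt(max(abs(r - 100)), 1)   # the torso loop, not the arm
  }
})

test_that("planes outside the mesh raise an empty-slice error", {
  mesh <- make_cylinder_mesh(radius = 10, zmin = 0, zmax = 20)
  expect_error(extract_slice(mesh, 25), class = "torsometry_empty_slice_error")
  expect_error(extract_slice(mesh, -5), class = "torsometry_empty_slice_error")
})

test_that("angular masks remove points and bridge the gap", {
  ct <- make_circle(r = 50, n = 360)
  expect_identical(exclude_sector(ct, list()), ct)
  masked <- exclude_sector(ct, list(c(80, 100)))
  ang <- atan2(masked[, 2], masked[, 1]) * 180 / pi
  # original points in (80, 100) are gone; bridge points lie on the chord
  r <- sqrt(rowSums(unclass(masked)^2))
  in_sector <- ang > 81 & ang < 99
  expect_true(all(r[in_sector] < 50 - 0.1))    # chord is strictly inside
  expect_gt(sum(in_sector), 5)                 # but the gap is bridged
  expect_match(torso_warnings(masked), "masked", all = FALSE)
  # roughly 20 degrees of points removed (one per degree of sampling)
  n_removed <- 360 - (nrow(masked) - sum(in_sector))
  expect_lte(abs(n_removed - 20), 3)
})

test_that("masks covering 180 degrees or more are rejected", {
  ct <- make_circle(r = 50)
  expect_error(exclude_sector(ct, list(c(0, 100), c(120, 220))),
               class = "torsometry_validation_error")
})

test_that("raw_contour validates its invariants", {
  expect_error(raw_contour(rbind(c(0, 0), c(1, 1))),
               class = "torsometry_validation_error")    # too few points
  th <- seq(0, 2 * pi, length.out = 40)[-40]
  expect_error(raw_contour(cbind(cos(th), sin(th)), level = "X9"),
               class = "torsometry_validation_error")    # bad level
  # closing duplicate and consecutive duplicates are dropped
  pts <- cbind(100 * cos(th), 100 * sin(th))
  ct <- raw_contour(rbind(pts, pts[1, ]))
  expect_equal(nrow(ct), 39)
  # a self-intersecting bowtie-like loop is rejected
  tt <- seq(0, 2 * pi, length.out = 80)[-80]
  bow <- cbind(cos(tt), sin(2 * tt) * 2)
  expect_error(raw_contour(bow), class = "torsometry_validation_error")
})
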