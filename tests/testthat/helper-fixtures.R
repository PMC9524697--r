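# Fixtures built in code: simple contours, cylinder meshes, direct grid
# constructors for oracle tests.

make_circle <- function(r = 100, center = c(0, 0), n = 360, phase = 0) {
  th <- (seq_len(n) - 1) * 2 * pi / n + phase
  raw_contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)))
}

make_ellipse <- function(a = 110, b = 90, center = c(0, 0), rot = 0, n = 360) {
  th <- (seq_len(n) - 1) * 2 * pi / n
  x <- a * cos(th); y <- b * sin(th)
  rr <- rot * pi / 180
  raw_contour(cbind(center[1] + x * cos(rr) - y * sin(rr),
                    center[2] + x * sin(rr) + y * cos(rr)))
}

# square [-s, s]^2 sampled along edges, counterclockwise, with points
# exactly at the edge midpoints and corners
make_square <- function(s = 1, per_side = 16) {
  t <- seq(-s, s, length.out = per_side + 1)[-(per_side + 1)]
  pts <- rbind(cbind(s, t),          # right edge, upward
               cbind(-t, s),         # top edge, leftward
               cbind(-s, -t),        # left edge, downward
               cbind(t, -s))         # bottom edge, rightward
  raw_contour(pts)
}

# closed vertical cylinder mesh (capped), axis = z
make_cylinder_mesh <- function(radius = 10, zmin = 0, zmax = 10, n_seg = 256,
                               center = c(0, 0)) {
  th <- (seq_len(n_seg) - 1) * 2 * pi / n_seg
  ring <- cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
  verts <- rbind(cbind(ring, zmin), cbind(ring, zmax),
                 c(center, zmin), c(center, zmax))
  i <- seq_len(n_seg); j <- c(2:n_seg, 1)
  side <- rbind(cbind(i, j, n_seg + j), cbind(i, n_seg + j, n_seg + i))
  cb <- 2 * n_seg + 1; ct <- 2 * n_seg + 2
  caps <- rbind(cbind(j, i, cb), cbind(n_seg + i, n_seg + j, ct))
  torso_mesh(verts, rbind(side, caps))
}

# merge two meshes into one vertex/face soup
merge_meshes <- function(m1, m2) {
  torso_mesh(rbind(m1$vertices, m2$vertices),
             rbind(m1$faces, m2$faces + nrow(m1$vertices)))
}

# build an aligned_contour directly from 361 grid radii (oracle tests)
make_aligned <- function(r361, level = NA_character_) {
  stopifnot(length(r361) == 361)
  r361[361] <- r361[1]
  structure(list(theta = -180:180, r = r361, mean_radius = mean(r361),
                 sp_angle = 0, rotation_applied = 0, level = level),
            class = "aligned_contour")
}

# smooth random star-shaped radius function on the closed grid -180..180
random_star_radii <- function(base = 100, n_harm = 6, amp = 0.15) {
  th <- (-180:180) * pi / 180
  r <- rep(base, 361)
  for (k in seq_len(n_harm)) {
    r <- r + base * amp / k * (runif(1, -1, 1) * cos(k * th) +
                               runif(1, -1, 1) * sin(k * th))
  }
  pmax(r, base * 0.2)
}

# build an rr_profile directly from branch vectors (oracle tests)
make_profile <- function(rr_right, rr_left) {
  structure(list(rr = NULL, rr_right = rr_right, rr_left = rr_left,
                 mean_radius = 100, level = NA_character_),
            class = "rr_profile")
}

shoelace_area_of <- function(ct) {
  x <- ct[, 1]; y <- ct[, 2]; n <- length(x); j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# random mirror-symmetric synthetic spec (no hump, midline dip)
random_symmetric_spec <- function(n_points = 360) {
  torso_spec(base_a = runif(1, 150, 190), base_b = runif(1, 100, 140),
             superellipse_exponent = runif(1, 2, 3),
             dip_depth = runif(1, 5, 20), dip_width = runif(1, 8, 25),
             dip_angle = 0, hump_amplitude = 0, n_points = n_points)
}
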