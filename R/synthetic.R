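# Parametric synthetic torsos with known ground truth: a superellipse base
# cross-section, a posterior spinous-process dip, and one or more one-sided
# rib-hump bumps whose amplitude peaks at a chosen apex level and falls off
# as a Gaussian along the vertical axis.

#' Specify a synthetic torso
#'
#' The radius model of a cross-section at vertebral level `l` is
#' `r(theta) = se(theta; a, b, p) - dip_depth g(theta - dip_angle; dip_width)
#' + h(l) g(theta - hump_angle; hump_width) + noise`, where `se` is the
#' superellipse radius, `g` a Gaussian bump of unit peak (width = standard
#' deviation in degrees), and `h(l) = hump_amplitude exp(-(l - apex)^2 /
#' (2 apex_spread^2))` with levels counted as indices 1 (C7) .. 18 (L5).
#' Angles are SP offsets: 0 = posterior midline, positive = right side.
#' The hump parameters may be vectors to superpose several curves (e.g. a
#' double thoracic + lumbar pattern).
#'
#' @param base_a lateral semi-axis of the base superellipse (mm).
#' @param base_b anterior-posterior semi-axis (mm).
#' @param superellipse_exponent shape exponent (2 = ellipse; larger = boxier).
#' @param dip_depth SP dip amplitude (mm, >= 0).
#' @param dip_width dip Gaussian width (degrees).
#' @param dip_angle dip center as SP offset (degrees; 0 = posterior midline).
#' @param hump_amplitude peak rib-hump amplitude(s) (mm, >= 0).
#' @param hump_angle hump center(s) as signed SP offset (degrees; positive =
#'   right side).
#' @param hump_width hump Gaussian width(s) (degrees).
#' @param apex_level level label(s) where each hump peaks.
#' @param apex_spread Gaussian falloff of each hump along the axis, in levels.
#' @param noise_sd radial Gaussian noise (mm).
#' @param seed RNG seed for the noise.
#' @param n_points contour samples per slice (>= 90; a multiple of 4 keeps
#'   the sampling symmetric about both midlines).
#' @return object of class `torso_spec` (validated parameter list).
#' @export
torso_spec <- function(base_a = 170, base_b = 120, superellipse_exponent = 2.5,
                       dip_depth = 12, dip_width = 12, dip_angle = 0,
                       hump_amplitude = 0, hump_angle = 50, hump_width = 25,
                       apex_level = "T8", apex_spread = 2,
                       noise_sd = 0, seed = 1L, n_points = 360L) {
  spec <- list(base_a = base_a, base_b = base_b,
               superellipse_exponent = superellipse_exponent,
               dip_depth = dip_depth, dip_width = dip_width,
               dip_angle = dip_angle,
               hump_amplitude = hump_amplitude, hump_angle = hump_angle,
               hump_width = hump_width, apex_level = apex_level,
               apex_spread = apex_spread,
               noise_sd = noise_sd, seed = as.integer(seed),
               n_points = as.integer(n_points))
  if (base_a <= 0 || base_b <= 0) validation_error("base semi-axes must be positive")
  if (superellipse_exponent <= 0) validation_error("superellipse exponent must be positive")
  if (dip_depth < 0 || any(hump_amplitude < 0))
    validation_error("dip_depth and hump_amplitude must be >= 0")
  if (dip_width <= 0 || any(hump_width <= 0))
    validation_error("bump widths must be positive")
  if (spec$n_points < 90) validation_error("n_points must be >= 90")
  if (noise_sd < 0) validation_error("noise_sd must be >= 0")
  nh <- length(hump_amplitude)
  for (f in c("hump_angle", "hump_width", "apex_level", "apex_spread"))
    spec[[f]] <- rep(spec[[f]], length.out = nh)
  level_index(spec$apex_level)  # validates labels
  structure(spec, class = "torso_spec")
}

#' @export
print.torso_spec <- function(x, ...) {
  cat(sprintf(
    "torso_spec: superellipse %g x %g mm (p = %g), dip %g mm @ %g deg, %d hump(s), noise %g mm\n",
    x$base_a, x$base_b, x$superellipse_exponent, x$dip_depth, x$dip_angle,
    sum(x$hump_amplitude > 0), x$noise_sd))
  invisible(x)
}

# superellipse radius at SP-offset angles (degrees); b along the
# posterior-anterior direction, a lateral
#' @keywords internal
#' @noRd
superellipse_r <- function(offset_deg, a, b, p) {
  # offset 0 = posterior (-y); geometric angle = offset - 90
  g <- (offset_deg - 90) * pi / 180
  (abs(cos(g) / a)^p + abs(sin(g) / b)^p)^(-1 / p)
}

# unit-peak Gaussian bump in wrapped angular distance
#' @keywords internal
#' @noRd
ang_gauss <- function(offset_deg, center, width) {
  d <- wrap180(offset_deg - center)
  exp(-d^2 / (2 * width^2))
}

# hump amplitude at a level (sum over superposed curves); lvl may be a
# continuous level index
#' @keywords internal
#' @noRd
hump_at_level <- function(spec, lvl_index) {
  a_ix <- level_index(spec$apex_level)
  amps <- vapply(seq_along(spec$hump_amplitude), function(j)
    spec$hump_amplitude[j] *
      exp(-(lvl_index - a_ix[j])^2 / (2 * spec$apex_spread[j]^2)), 0)
  amps
}

# deterministic noiseless radius model at SP-offset angles for one level
#' @keywords internal
#' @noRd
model_radius <- function(spec, offset_deg, lvl_index) {
  r <- superellipse_r(offset_deg, spec$base_a, spec$base_b,
                      spec$superellipse_exponent)
  r <- r - spec$dip_depth * ang_gauss(offset_deg, spec$dip_angle, spec$dip_width)
  amps <- hump_at_level(spec, lvl_index)
  for (j in seq_along(amps))
    r <- r + amps[j] * ang_gauss(offset_deg, spec$hump_angle[j], spec$hump_width[j])
  r
}

#' Generate one synthetic cross-section with ground truth
#'
#' Samples the radius model at `n_points` uniformly spaced angles, adds
#' seeded Gaussian radial noise, and returns the contour together with the
#' ground truth the generator knows exactly: the true SP (dip) angle, the
#' hump side, and the left/right fan areas of the noiseless model computed
#' by quadrature at 0.01-degree resolution about the dense point centroid
#' (the same split the pipeline uses, at effectively continuous resolution).
#'
#' @param spec a [torso_spec].
#' @param level vertebral level label (default the first `apex_level`).
#' @return list with `contour` (a [raw_contour]) and `truth`: `sp_offset_deg`
#'   (true dip center as SP offset), `sp_geometric_deg`, `hump_side`
#'   (`"right"`, `"left"` or `"none"` from the signed amplitude-weighted hump
#'   angle at this level), `hump_amplitude_level` (mm), `la_true`, `ra_true`
#'   (mm^2 quadrature fan areas left/right of the dip axis), `level`.
#' @export
generate_contour <- function(spec, level = spec$apex_level[1]) {
  li <- level_index(level)
  offs <- seq(0, 360 - 360 / spec$n_points, by = 360 / spec$n_points)
  r <- model_radius(spec, offs, li)
  if (any(r <= 0))
    validation_error("radius model non-positive: dip too deep for the base shape")
  if (spec$noise_sd > 0) {
    # per-level seed so contours are reproducible independent of call order
    set.seed((spec$seed + 1009L * li) %% .Machine$integer.max)
    r <- r + stats::rnorm(length(r), 0, spec$noise_sd)
    if (any(r <= 0)) validation_error("noise drove the radius non-positive")
  }
  g <- (offs - 90) * pi / 180
  pts <- cbind(r * cos(g), r * sin(g))
  contour <- raw_contour(pts, level = if (level %in% LEVEL_LABELS) level else NA,
                         check_simple = FALSE)

  amps <- hump_at_level(spec, li)
  atot <- sum(amps)
  side <- "none"
  if (atot > 1e-12) {
    mean_angle <- sum(amps * wrap180(spec$hump_angle)) / atot
    side <- if (mean_angle > 0) "right" else if (mean_angle < 0) "left" else "none"
  }
  truth <- c(quadrature_truth(spec, li),
             list(sp_offset_deg = spec$dip_angle,
                  sp_geometric_deg = wrap180(spec$dip_angle - 90),
                  hump_side = side, hump_amplitude_level = atot,
                  level = level))
  list(contour = contour, truth = truth)
}

# dense-quadrature left/right fan areas of the noiseless model, mirroring
# the pipeline's centroid + dip-axis split at 0.01-degree resolution
#' @keywords internal
#' @noRd
quadrature_truth <- function(spec, lvl_index, step = 0.01) {
  offs <- seq(0, 360 - step, by = step)
  r <- model_radius(spec, offs, lvl_index)
  g <- (offs - 90) * pi / 180
  x <- r * cos(g); y <- r * sin(g)
  ctr <- c(mean(x), mean(y))
  dx <- x - ctr[1]; dy <- y - ctr[2]
  rc <- sqrt(dx^2 + dy^2)
  thc <- atan2(dy, dx) * 180 / pi
  # dip direction as seen from the centroid: radius minimum in the
  # posterior sector around the nominal dip
  post <- abs(ang_diff(thc, spec$dip_angle - 90)) <= 60
  sp_dir <- thc[post][which.min(rc[post])]
  off_c <- wrap180(thc - sp_dir)             # offset from dip axis, right positive
  o <- order(off_c)
  off_s <- off_c[o]; r_s <- rc[o]
  # insert exact boundary samples at -180, 0, 180 so the split is a partition
  ext_th <- c(off_s - 360, off_s, off_s + 360)
  ext_r <- rep(r_s, 3)
  bnd <- c(-180, 0, 180)
  rb <- stats::approx(ext_th, ext_r, xout = bnd, ties = "ordered")$y
  off_s <- c(off_s, bnd); r_s <- c(r_s, rb)
  o <- order(off_s)
  off_s <- off_s[o]; r_s <- r_s[o]
  tri <- function(sel_lo, sel_hi) {
    ix <- which(off_s >= sel_lo & off_s <= sel_hi)
    rr <- r_s[ix]
    dth <- diff(off_s[ix]) * pi / 180
    sum(abs(rr[-length(rr)] * rr[-1]) * sin(dth)) / 2
  }
  list(ra_true = tri(0, 180), la_true = tri(-180, 0))
}

#' Generate a full synthetic torso (18 levels, optional mesh)
#'
#' One contour per vertebral level C7..L5, with the hump amplitude following
#' the apex profile of the spec, plus per-level ground truth. Level heights
#' come from the landmark heights via [interpolate_levels]. Optionally a
#' watertight triangulated mesh is lofted through the continuous radius
#' model (rings every `ring_step` mm, fan-capped top and bottom) so the
#' slice-extraction stage can be exercised end to end.
#'
#' @param spec a [torso_spec].
#' @param landmarks c7/t8/l5 heights in mm (default `c(c7 = 480, t8 = 320,
#'   l5 = 140)`, a plausible adolescent torso).
#' @param mesh logical: also build the lofted mesh (default FALSE).
#' @param ring_step vertical ring spacing of the mesh in mm (default 5).
#' @return object of class `synthetic_torso`: list with `contours` (named
#'   list of [raw_contour]), `truth` (data frame, one row per level),
#'   `levels` (the level/height table), `landmarks`, `spec`, and `mesh` (a
#'   [torso_mesh] or NULL).
#' @export
generate_torso <- function(spec, landmarks = c(c7 = 480, t8 = 320, l5 = 140),
                           mesh = FALSE, ring_step = 5) {
  lv <- interpolate_levels(landmarks)
  gen <- lapply(LEVEL_LABELS, function(l) generate_contour(spec, l))
  contours <- lapply(gen, `[[`, "contour")
  names(contours) <- LEVEL_LABELS
  truth <- do.call(rbind, lapply(gen, function(g)
    data.frame(level = g$truth$level, sp_offset_deg = g$truth$sp_offset_deg,
               hump_side = g$truth$hump_side,
               hump_amplitude = g$truth$hump_amplitude_level,
               la_true = g$truth$la_true, ra_true = g$truth$ra_true)))
  m <- if (mesh) loft_mesh(spec, lv, ring_step = ring_step) else NULL
  structure(list(contours = contours, truth = truth, levels = lv,
                 landmarks = landmarks, spec = spec, mesh = m),
            class = "synthetic_torso")
}

#' @export
print.synthetic_torso <- function(x, ...) {
  cat(sprintf("synthetic_torso: 18 levels, heights %.0f..%.0f mm%s\n",
              min(x$levels$height), max(x$levels$height),
              if (is.null(x$mesh)) "" else ", with mesh"))
  invisible(x)
}

# continuous level index as a function of height (piecewise linear through
# the three landmarks, linearly extrapolated beyond C7 and L5)
#' @keywords internal
#' @noRd
height_to_level_index <- function(h, landmarks) {
  lm <- as.list(landmarks); names(lm) <- tolower(names(lm))
  c7 <- lm$c7; t8 <- lm$t8; l5 <- lm$l5
  ifelse(h >= t8,
         1 + 8 * (c7 - h) / (c7 - t8),
         9 + 9 * (t8 - h) / (t8 - l5))
}

#' @keywords internal
#' @noRd
loft_mesh <- function(spec, level_table, ring_step = 5) {
  lmk <- c(c7 = max(level_table$height), t8 = level_table$height[9],
           l5 = min(level_table$height))
  z0 <- lmk["l5"] - 3 * ring_step
  z1 <- lmk["c7"] + 3 * ring_step
  # small offset keeps level planes from coinciding with mesh rings
  zs <- seq(z0, z1, by = ring_step) + 0.37 * ring_step
  n <- spec$n_points
  offs <- seq(0, 360 - 360 / n, by = 360 / n)
  g <- (offs - 90) * pi / 180
  verts <- do.call(rbind, lapply(zs, function(z) {
    r <- model_radius(spec, offs, height_to_level_index(z, lmk))
    if (any(r <= 0)) validation_error("radius model non-positive while lofting mesh")
    cbind(r * cos(g), r * sin(g), z)
  }))
  nz <- length(zs)
  quads <- do.call(rbind, lapply(seq_len(nz - 1), function(k) {
    a <- (k - 1) * n + seq_len(n)          # ring k
    b <- a + n                             # ring k + 1
    a2 <- a[c(2:n, 1)]; b2 <- b[c(2:n, 1)]
    rbind(cbind(a, a2, b2), cbind(a, b2, b))
  }))
  # fan caps through center vertices
  cb <- nrow(verts) + 1L; ct <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, zs[1]), c(0, 0, zs[nz]))
  bot <- (0) * n + seq_len(n)
  top <- (nz - 1) * n + seq_len(n)
  caps <- rbind(cbind(bot[c(2:n, 1)], bot, cb),
                cbind(top, top[c(2:n, 1)], ct))
  torso_mesh(verts, rbind(quads, caps))
}

#' Named synthetic presets
#'
#' Three scenario templates ship with the package (parameters in
#' `inst/extdata/presets.yaml`): `healthy` (mild dip, no hump),
#' `thoracic_t8` (single right thoracic hump peaking at T8), and
#' `double_curve` (right thoracic T9 + left lumbar L2 humps). These are
#' plausible deformity phenotypes for exercising the pipeline, not
#' reconstructions of any individual.
#'
#' @param name preset name.
#' @param ... overrides passed on to [torso_spec] (e.g. `seed`, `noise_sd`).
#' @return a [torso_spec].
#' @export
preset_spec <- function(name = c("healthy", "thoracic_t8", "double_curve"), ...) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets.yaml", package = "torsometry")
  presets <- yaml::read_yaml(path)
  if (!name %in% names(presets)) validation_error(paste0("unknown preset: ", name))
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(torso_spec, args)
}
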