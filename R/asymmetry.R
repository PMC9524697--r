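# Per-slice asymmetry parameters: relative-radius profiles, the left-right
# ordinary-least-squares fit and its coefficient of determination, triangle-
# fan sector areas, left-right and backside area asymmetries, and vertical
# distance profiles from the vertebral-body line.

#' Relative-radius profile of an aligned slice
#'
#' Each grid radius is normalized by the mean contour radius and scaled by
#' 100, giving the dimensionless relative radius
#' `RR(theta) = 100 r(theta) / r_m`. The profile is split at the SP into a
#' right branch (offsets 0..180) and a left branch (offsets 0..-180); the
#' two branches share the SP value at offset 0 and the anterior value at
#' offset +/-180.
#'
#' @param aligned an `aligned_contour`.
#' @return object of class `rr_profile`: list with `rr` (361 values on the
#'   full grid -180..180), `rr_right` (181 values, offsets 0..180),
#'   `rr_left` (181 values, offsets 0, -1, .., -180), `mean_radius` (mm).
#' @export
relative_radius <- function(aligned) {
  rr <- 100 * aligned$r / aligned$mean_radius
  names(rr) <- aligned$theta
  right <- rr[match(0:180, aligned$theta)]
  left <- rr[match(0:-180, aligned$theta)]
  out <- structure(list(rr = rr, rr_right = unname(right),
                        rr_left = unname(left),
                        mean_radius = aligned$mean_radius,
                        level = aligned$level),
                   class = "rr_profile")
  carry_warnings(out, aligned)
}

#' Left-right symmetry fit of a relative-radius profile
#'
#' Pairs the two branches by equal absolute SP offset and fits the ordinary
#' least-squares line `rr_left ~ rr_right`. For a perfectly symmetric slice
#' all pairs fall on the identity line y = x and the coefficient of
#' determination is 1; asymmetry disperses the points and lowers R-squared.
#' R-squared is computed from residuals about the *fitted* line
#' (`1 - SS_res / SS_tot`). The residual sum about the identity line is also
#' reported (`r_squared_identity`), since proximity to y = x is the
#' theoretical symmetry criterion; it can be negative for strongly deformed
#' slices and is reported for diagnostics only.
#'
#' A constant profile has zero abscissa variance; by convention this exactly
#' symmetric degenerate case returns slope 1, intercept 0, R-squared 1, with
#' a recorded warning.
#'
#' @param profile an `rr_profile`.
#' @param sector `"full"` to pair all 181 offsets 0..180, or a numeric
#'   backside separation in degrees to pair only offsets 0..separation.
#' @param include_ends logical; include the shared SP (offset 0) and, for
#'   the full sector, the shared anterior (+/-180) pair (default TRUE).
#' @return object of class `symmetry_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `r_squared_identity`, `n_points`, `sector`.
#' @export
fit_left_right <- function(profile, sector = "full", include_ends = TRUE) {
  if (identical(sector, "full")) {
    sep <- 180
    sector_label <- "full"
  } else {
    sep <- round(as.numeric(sector))
    if (is.na(sep) || sep <= 0 || sep >= 180)
      validation_error("backside sector separation must lie in (0, 180)")
    sector_label <- paste0("backside_", sep)
  }
  ix <- seq_len(sep + 1)
  x <- profile$rr_right[ix]
  y <- profile$rr_left[ix]
  if (!include_ends) {
    drop <- c(1L, if (sep == 180) sep + 1L)
    x <- x[-drop]; y <- y[-drop]
  }
  n <- length(x)
  if (n < 3) validation_error("left-right fit needs at least 3 paired points")
  sxx <- sum((x - mean(x))^2)
  warn <- NULL
  if (sxx < .Machine$double.eps * 100 * n) {
    slope <- 1; intercept <- 0; r2 <- 1; r2_id <- 1
    warn <- "constant profile: zero abscissa variance, perfect-symmetry convention applied"
  } else {
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mean(x)
    fitted <- intercept + slope * x
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot < .Machine$double.eps * 100 * n) {
      r2 <- 1; r2_id <- 1  # degenerate: constant ordinate
    } else {
      r2 <- 1 - sum((y - fitted)^2) / ss_tot
      r2_id <- 1 - sum((y - x)^2) / ss_tot
    }
  }
  out <- structure(list(slope = slope, intercept = intercept,
                        r_squared = r2, r_squared_identity = r2_id,
                        n_points = n, sector = sector_label),
                   class = "symmetry_fit")
  if (!is.null(warn)) out <- add_warning(out, warn)
  out
}

#' @export
print.symmetry_fit <- function(x, ...) {
  cat(sprintf("symmetry_fit (%s): y = %.4f x + %.4f, R^2 = %.4f (n = %d)\n",
              x$sector, x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Triangle-fan area of an angular sector
#'
#' The area between the contour and the centroid over an angular sector is
#' computed by splitting the sector into triangles: the centroid (origin of
#' the aligned frame) and two consecutive grid points form each triangle,
#' whose area is half the absolute cross product of its two radius vectors.
#'
#' @param aligned an `aligned_contour`.
#' @param sector length-2 numeric `c(from, to)` in grid offsets within
#'   -180..180, `from < to`. The full contour is `c(-180, 180)`.
#' @return area in mm^2 (0 for an empty sector).
#' @export
fan_area <- function(aligned, sector = c(-180, 180)) {
  lo <- round(sector[1]); hi <- round(sector[2])
  if (lo < -180 || hi > 180 || lo > hi)
    validation_error("sector must satisfy -180 <= from <= to <= 180")
  if (hi == lo) return(0)
  offs <- lo:hi
  r <- grid_r(aligned, offs)
  sin1 <- sin(pi / 180)
  sum(abs(r[-length(r)] * r[-1])) * sin1 / 2
}

#' Area asymmetry of two sector areas
#'
#' `|LA - RA| / (LA + RA)`: 0 for equal areas, 1 when one side vanishes.
#'
#' @param la,ra left and right areas (mm^2), non-negative, not both zero.
#' @return dimensionless asymmetry in `[0, 1]`.
#' @export
area_asymmetry <- function(la, ra) {
  if (la < 0 || ra < 0) validation_error("areas must be non-negative")
  if (la + ra <= 0) validation_error("both areas are zero")
  abs((la - ra) / (la + ra))
}

#' Backside metrics between the BLSP and BRSP anchors
#'
#' Over the two backside segments (SP to BRSP on the right, SP to BLSP on
#' the left): the fan areas feed the backside area asymmetry; for every grid
#' angle the vertical distance from the vertebral-body line down to the
#' contour point gives the `Dist_VB` profile (larger where the back
#' protrudes, as over a rib hump); and the relative radii over the same
#' segments give the `rad_back` profiles. All profiles are indexed by the
#' absolute angular offset from the SP (0..separation), so the SP sits at
#' offset 0 in both.
#'
#' @param aligned an `aligned_contour`.
#' @param anchors anchor list from [locate_backside_anchors].
#' @param vb vertebral-body line from [estimate_vb_line].
#' @return list with `backside_area_asym`, `la_backside`, `ra_backside`
#'   (mm^2), `dist_vb_left`, `dist_vb_right` (mm, length separation+1),
#'   `rad_back_left`, `rad_back_right` (relative-radius units).
#' @export
backside_metrics <- function(aligned, anchors, vb) {
  sep <- anchors$separation
  la_b <- fan_area(aligned, c(-sep, 0))
  ra_b <- fan_area(aligned, c(0, sep))
  rr <- relative_radius(aligned)
  offs <- 0:sep
  r_right <- grid_r(aligned, offs)
  r_left <- grid_r(aligned, -offs)
  cosv <- cos(offs * pi / 180)
  # contour point at offset phi sits at y = -r(phi) cos(phi) in the aligned
  # frame; Dist_VB is measured downward from the VB line at y = vb_height
  dist_r <- r_right * cosv + vb$vb_height
  dist_l <- r_left * cosv + vb$vb_height
  list(backside_area_asym = area_asymmetry(la_b, ra_b),
       la_backside = la_b, ra_backside = ra_b,
       dist_vb_left = dist_l, dist_vb_right = dist_r,
       rad_back_left = rr$rr_left[seq_len(sep + 1)],
       rad_back_right = rr$rr_right[seq_len(sep + 1)])
}

#' Full asymmetry assessment of one aligned slice
#'
#' Composes the per-slice parameters: the left-right OLS fit and R-squared
#' over the full sides and over the backside segments, the left and right
#' fan areas and their asymmetry, and the backside distance/radius profiles.
#'
#' @param aligned an `aligned_contour`.
#' @param anchors from [locate_backside_anchors]; default separation 70.
#' @param vb from [estimate_vb_line]; default spinous-process length 40 mm.
#' @return object of class `slice_asymmetry`: list with `level`,
#'   `r_squared_full`, `r_squared_backside`, `slope_full`, `intercept_full`,
#'   `la`, `ra` (mm^2), `lr_area_asym`, `backside_area_asym`, the profile
#'   vectors from [backside_metrics], `mean_radius`, `rotation_applied`, and
#'   recorded warnings.
#' @export
assess_slice <- function(aligned,
                         anchors = locate_backside_anchors(aligned),
                         vb = estimate_vb_line(aligned)) {
  profile <- relative_radius(aligned)
  fit_full <- fit_left_right(profile, "full")
  fit_back <- fit_left_right(profile, anchors$separation)
  la <- fan_area(aligned, c(-180, 0))
  ra <- fan_area(aligned, c(0, 180))
  back <- backside_metrics(aligned, anchors, vb)
  out <- structure(list(
    level = aligned$level,
    r_squared_full = fit_full$r_squared,
    r_squared_backside = fit_back$r_squared,
    r_squared_identity = fit_full$r_squared_identity,
    slope_full = fit_full$slope,
    intercept_full = fit_full$intercept,
    slope_backside = fit_back$slope,
    intercept_backside = fit_back$intercept,
    la = la, ra = ra,
    lr_area_asym = area_asymmetry(la, ra),
    backside_area_asym = back$backside_area_asym,
    la_backside = back$la_backside, ra_backside = back$ra_backside,
    dist_vb_left = back$dist_vb_left, dist_vb_right = back$dist_vb_right,
    rad_back_left = back$rad_back_left, rad_back_right = back$rad_back_right,
    mean_radius = aligned$mean_radius,
    rotation_applied = aligned$rotation_applied,
    separation = anchors$separation,
    sp_offset = vb$sp_offset), class = "slice_asymmetry")
  out <- carry_warnings(out, aligned)
  out <- carry_warnings(out, fit_full)
  carry_warnings(out, fit_back)
}

#' @export
print.slice_asymmetry <- function(x, ...) {
  cat(sprintf(
    "slice_asymmetry level %s: R^2 full %.4f / backside %.4f, LR asym %.4f, backside asym %.4f\n",
    x$level, x$r_squared_full, x$r_squared_backside,
    x$lr_area_asym, x$backside_area_asym))
  invisible(x)
}

#' Run the whole per-slice chain on a raw contour
#'
#' Convenience wrapper: centroid, polar conversion, SP detection, two-step
#' alignment, 1-degree resampling, anchors, VB line, and [assess_slice].
#'
#' @param contour a [raw_contour].
#' @param separation backside anchor separation in degrees (default 70).
#' @param sp_offset assumed spinous-process length in mm (default 40).
#' @param sp_search posterior search sector for the SP dip (geometric
#'   degrees, default `c(-150, -30)`).
#' @param sp_smooth moving-average pre-filter window for SP detection in
#'   degrees (0 = off).
#' @param masks optional angular masks passed to [exclude_sector].
#' @return a `slice_asymmetry`.
#' @export
analyze_contour <- function(contour, separation = 70, sp_offset = 40,
                            sp_search = c(-150, -30), sp_smooth = 0,
                            masks = list()) {
  contour <- exclude_sector(contour, masks)
  polar <- to_polar(contour)
  sp <- detect_sp(polar, search_sector = sp_search, smooth_window = sp_smooth)
  aligned <- align_slice(polar, sp$angle)
  if (sp$low_confidence)
    aligned <- add_warning(aligned, sprintf(
      "low-confidence SP detection (flat minimum spanning %.1f deg)", sp$flat_span))
  grid <- resample_angular(aligned)
  assess_slice(grid,
               anchors = locate_backside_anchors(grid, separation),
               vb = estimate_vb_line(grid, sp_offset))
}
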