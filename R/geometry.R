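# Polar-coordinate geometry of a single slice: centroid, polar conversion,
# spinous-process (SP) detection, two-step rotational alignment, angular
# resampling onto the 1-degree grid, backside anchors and vertebral-body line.
#
# Two angular frames are used. The *geometric* frame is the standard
# mathematical angle of the raw slice (0 = +x, 90 = +y = anterior, -90 =
# posterior). The *aligned offset* frame indexes the 1-degree grid by the
# signed angular offset from the SP: offset 0 is the SP (posterior midline),
# positive offsets 0..180 sweep the right body side, negative offsets the
# left side; offset +/-180 is the anterior midline.

#' Centroid of a contour (point mean)
#'
#' The slice centroid is defined as the arithmetic mean of all contour
#' points (not the area centroid): the contour is what the scanner measures,
#' so its point density is the natural weighting.
#'
#' @param contour a [raw_contour] or two-column point matrix.
#' @return length-2 numeric `c(x, y)` in mm.
#' @export
compute_centroid <- function(contour) {
  c(mean(contour[, 1]), mean(contour[, 2]))
}

#' Convert a contour to centroid-origin polar coordinates
#'
#' Translates the contour so `origin` is at (0, 0) and expresses each point
#' as (angle, radius), sorted by angle. The origin must lie strictly inside
#' the loop, and the loop should be star-shaped about it (every ray from the
#' origin crosses the contour once). If it is not, the outer silhouette is
#' kept: within each 1-degree angular bin only the largest radius survives,
#' and a warning is recorded on the result.
#'
#' @param contour a [raw_contour].
#' @param origin length-2 numeric; defaults to [compute_centroid] of the
#'   contour.
#' @return object of class `polar_contour`: data frame with columns
#'   `theta` (geometric degrees in (-180, 180], sorted) and `r` (mm), with
#'   the origin stored in attribute `origin`.
#' @export
to_polar <- function(contour, origin = compute_centroid(contour)) {
  pts <- unclass(contour)[, 1:2, drop = FALSE]
  if (!point_in_polygon(origin, pts))
    geometry_error("polar origin lies outside the contour")
  dx <- pts[, 1] - origin[1]
  dy <- pts[, 2] - origin[2]
  r <- sqrt(dx^2 + dy^2)
  if (any(r == 0)) geometry_error("a contour point coincides with the origin")
  theta <- atan2(dy, dx) * 180 / pi          # in (-180, 180]
  warn <- NULL

  # star-shape check: along the loop, angles must wind monotonically once
  dth <- wrap180(diff(c(theta, theta[1])))
  if (!(all(dth >= 0) || all(dth <= 0))) {
    # keep the outer silhouette: max radius per 1-degree bin
    bin <- floor(wrap360(theta))
    keep <- unlist(lapply(split(seq_along(r), bin), function(ix) ix[which.max(r[ix])]),
                   use.names = FALSE)
    theta <- theta[keep]; r <- r[keep]
    warn <- "contour not star-shaped about origin; kept largest radius per 1-degree bin"
  }
  o <- order(theta)
  out <- structure(data.frame(theta = theta[o], r = r[o]),
                   class = c("polar_contour", "data.frame"),
                   origin = origin, level = attr(contour, "level"))
  out <- carry_warnings(out, contour)
  if (!is.null(warn)) out <- add_warning(out, warn)
  out
}

#' Reconstruct Cartesian points from a polar contour
#'
#' Inverse of [to_polar] (up to point ordering): maps each (theta, r) back
#' to the original coordinate frame.
#'
#' @param polar a `polar_contour`.
#' @return two-column matrix of (x, y) points.
#' @export
from_polar <- function(polar) {
  origin <- attr(polar, "origin")
  if (is.null(origin)) origin <- c(0, 0)
  th <- polar$theta * pi / 180
  cbind(x = origin[1] + polar$r * cos(th),
        y = origin[2] + polar$r * sin(th))
}

#' Detect the spinous-process dip on the posterior contour
#'
#' The skin landmark of the spinous process is the characteristic dip (local
#' radius minimum) on the posterior section of the slice. The detector
#' returns the angle of minimum radius within the posterior search sector;
#' ties are broken toward the posterior midline (-90 degrees). A flat
#' minimum spanning more than `flat_span` degrees (all radii within
#' `flat_tol` of the minimum) yields a low-confidence flag, and the
#' tie-break angle is returned.
#'
#' An optional circular moving-average pre-filter (`smooth_window`, degrees;
#' 0 = off) suppresses sample noise before the minimum search. For noisy
#' scans a window comparable to the expected dip width acts as a matched
#' filter and stabilizes the detected angle.
#'
#' @param polar a `polar_contour` in the geometric frame.
#' @param search_sector length-2 numeric, geometric degrees swept
#'   counterclockwise from the first to the second element; default the
#'   posterior 120-degree sector `c(-150, -30)`.
#' @param smooth_window moving-average window in degrees (0 disables).
#' @param flat_tol radius tolerance defining the flat set, as a fraction of
#'   the mean radius (default 1e-3).
#' @param flat_span angular span (degrees) of the flat set above which the
#'   detection is flagged low-confidence (default 30).
#' @param refine sub-sample refinement: fit a parabola through the minimum
#'   sample and its two angular neighbours and return its vertex (default
#'   TRUE). This keeps the detected angle continuous under smooth shape
#'   changes instead of hopping between samples.
#' @return list with elements `angle` (geometric degrees), `low_confidence`
#'   (logical) and `flat_span` (degrees actually spanned by the flat set).
#' @export
detect_sp <- function(polar, search_sector = c(-150, -30), smooth_window = 0,
                      flat_tol = 1e-3, flat_span = 30, refine = TRUE) {
  width <- wrap360(search_sector[2] - search_sector[1])
  if (width == 0) validation_error("empty SP search sector")
  th <- polar$theta
  r <- polar$r
  if (smooth_window > 0) r <- circular_smooth(th, r, smooth_window)
  off <- wrap360(th - search_sector[1])
  sel <- off <= width
  if (!any(sel)) geometry_error("no contour points inside the SP search sector")
  mid <- search_sector[1] + width / 2
  th_s <- th[sel]; r_s <- r[sel]
  tol <- flat_tol * mean(polar$r)
  flat <- r_s <= min(r_s) + tol
  span <- if (sum(flat) > 1) diff(range(wrap360(th_s[flat] - search_sector[1]))) else 0
  low <- span > flat_span
  angle <- if (low) {
    # degenerate flat minimum: fall back to the posterior midline
    th_s[which.min(abs(ang_diff(th_s, mid)))]
  } else {
    # numerical ties at the minimum are broken toward the posterior midline
    cand <- which(r_s <= min(r_s) + 1e-9 * mean(polar$r))
    best <- th_s[cand[which.min(abs(ang_diff(th_s[cand], mid)))]]
    if (refine) parabolic_refine(th, r, best) else best
  }
  list(angle = as.numeric(angle), low_confidence = low, flat_span = as.numeric(span))
}

# vertex of the parabola through the minimum sample at angle `at` and its
# two circular neighbours; falls back to `at` for degenerate curvature
#' @keywords internal
#' @noRd
parabolic_refine <- function(theta, r, at) {
  o <- order(theta)
  th <- theta[o]; rr <- r[o]
  n <- length(th)
  i <- which.min(abs(ang_diff(th, at)))
  im <- if (i == 1) n else i - 1
  ip <- if (i == n) 1 else i + 1
  x1 <- ang_diff(th[im], th[i]); x2 <- 0; x3 <- ang_diff(th[ip], th[i])
  y1 <- rr[im]; y2 <- rr[i]; y3 <- rr[ip]
  denom <- (x1 - x2) * (x1 - x3) * (x2 - x3)
  if (abs(denom) < .Machine$double.eps) return(th[i])
  a <- (x3 * (y2 - y1) + x2 * (y1 - y3) + x1 * (y3 - y2)) / denom
  b <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) / denom
  if (a <= 0) return(th[i])
  v <- -b / (2 * a)
  if (v < x1 || v > x3) return(th[i])
  wrap180(th[i] + v)
}

# circular moving average of r over +/- window/2 degrees (non-uniform samples)
#' @keywords internal
#' @noRd
circular_smooth <- function(theta, r, window) {
  o <- order(theta)
  th <- theta[o]; rr <- r[o]
  n <- length(th)
  ext_th <- c(th - 360, th, th + 360)
  ext_r <- c(rr, rr, rr)
  cs <- c(0, cumsum(ext_r))
  lo <- findInterval(th - window / 2, ext_th, left.open = TRUE) + 1L
  hi <- findInterval(th + window / 2, ext_th)
  lo_ix <- lo; hi_ix <- hi
  out <- (cs[hi_ix + 1] - cs[lo_ix]) / pmax(1L, hi_ix - lo_ix + 1L)
  res <- numeric(n)
  res[o] <- out
  res
}

#' Align a slice: maximal diameter horizontal, then SP to the bottom
#'
#' Rearranges the slice in two steps. First, the maximal diameter through
#' the centroid -- the angle maximizing `d(theta) = r(theta) + r(theta+180)`
#' on a 1-degree grid -- is rotated to the horizontal; of the two possible
#' orientations the one placing the SP in the lower half-plane is taken.
#' Second, a fine-tuning rotation puts the SP exactly below the centroid
#' (geometric angle -90). If that correction exceeds 45 degrees the SP
#' detection and the principal direction disagree strongly and a warning is
#' recorded. The total applied rotation is stored.
#'
#' @param polar a `polar_contour` in the geometric frame.
#' @param sp_angle geometric angle (degrees) of the detected SP, e.g. from
#'   [detect_sp].
#' @return a `polar_contour` in the *aligned offset* frame: column `theta`
#'   is now the signed offset from the SP (0 = SP, positive = right side),
#'   sorted; attribute `rotation_applied` gives the total rotation in
#'   degrees applied to the raw frame.
#' @export
align_slice <- function(polar, sp_angle) {
  grid <- resample_to_grid(polar$theta, polar$r)       # 0..359 at 1 degree
  d <- grid$r[1:180] + grid$r[181:360]
  dmax <- max(d)
  ties <- which(d >= dmax - 1e-12 * dmax)
  # tie-break: diameter closest to horizontal in the current frame
  star <- (ties - 1)[which.min(pmin(abs(ang_diff(ties - 1, 0)),
                                    abs(ang_diff(ties - 1, 180))))]
  rot1 <- -star
  # choose the 180-degree ambiguity putting the SP in the lower half
  sp1 <- wrap180(sp_angle + rot1)
  if (sp1 > 0) rot1 <- rot1 + 180
  sp1 <- wrap180(sp_angle + rot1)
  rot2 <- -90 - sp1
  warn <- if (abs(rot2) > 45)
    sprintf("SP fine-tune rotation %.1f deg exceeds 45 deg: SP and principal direction disagree", rot2)
  rot <- wrap180(rot1 + rot2)
  # offset frame: theta_off = geometric angle after rotation + 90
  off <- wrap180(polar$theta + rot + 90)
  o <- order(off)
  out <- structure(data.frame(theta = off[o], r = polar$r[o]),
                   class = c("polar_contour", "data.frame"),
                   origin = attr(polar, "origin"),
                   level = attr(polar, "level"),
                   frame = "aligned_offset",
                   rotation_applied = as.numeric(rot))
  out <- carry_warnings(out, polar)
  if (!is.null(warn)) out <- add_warning(out, warn)
  out
}

# linear interpolation (with wraparound) of scattered (theta, r) onto an
# integer-degree grid given as 0..359 (geometric) -- helper for align_slice.
#' @keywords internal
#' @noRd
resample_to_grid <- function(theta, r, grid = 0:359) {
  o <- order(theta)
  th <- theta[o]; rr <- r[o]
  ext_th <- c(th - 360, th, th + 360)
  ext_r <- c(rr, rr, rr)
  list(theta = grid,
       r = stats::approx(ext_th, ext_r, xout = wrap180(grid), ties = "ordered")$y)
}

#' Resample an aligned slice onto the uniform 1-degree grid
#'
#' Radii are linearly interpolated (with wraparound) onto the exact grid
#' 0, +/-1, ..., +/-180 degrees of SP offset, and the mean contour radius is
#' recomputed as the arithmetic mean over the grid. An angular gap larger
#' than `gap_warn` degrees between consecutive input samples (e.g. after arm
#' masking) is recorded as a warning.
#'
#' @param aligned a `polar_contour` in the aligned offset frame (from
#'   [align_slice]).
#' @param gap_warn gap threshold in degrees (default 10).
#' @return object of class `aligned_contour`: list with `theta`
#'   (-180..180, 361 values), `r` (mm), `mean_radius` (mm), `sp_angle` (0 by
#'   construction), `rotation_applied`, `level`.
#' @export
resample_angular <- function(aligned, gap_warn = 10) {
  th <- aligned$theta; r <- aligned$r
  o <- order(th)
  th <- th[o]; r <- r[o]
  gaps <- diff(c(th, th[1] + 360))
  grid <- -180:180
  ri <- resample_to_grid(th, r, grid = grid)$r
  # wraparound consistency is exact by construction
  ri[1] <- ri[361] <- (ri[1] + ri[361]) / 2
  out <- structure(list(theta = grid, r = ri, mean_radius = mean(ri),
                        sp_angle = 0,
                        rotation_applied = attr(aligned, "rotation_applied"),
                        level = attr(aligned, "level")),
                   class = "aligned_contour")
  out <- carry_warnings(out, aligned)
  if (max(gaps) > gap_warn)
    out <- add_warning(out, sprintf(
      "angular gap of %.1f deg in input samples; interpolated across", max(gaps)))
  if (any(ri <= 0)) geometry_error("non-positive radius after resampling")
  out
}

#' @export
print.aligned_contour <- function(x, ...) {
  cat(sprintf("aligned_contour: level %s, mean radius %.1f mm, rotation %.1f deg\n",
              x$level, x$mean_radius, x$rotation_applied))
  w <- torso_warnings(x)
  if (length(w)) cat(" warnings:", paste(w, collapse = "; "), "\n")
  invisible(x)
}

# radius at given integer offsets of the aligned grid
#' @keywords internal
#' @noRd
grid_r <- function(aligned, offsets) {
  aligned$r[match(offsets, aligned$theta)]
}

#' Locate the backside anchor points BLSP and BRSP
#'
#' Two anchors at equal polar-angle distance on either side of the SP bound
#' the backside segments used in the backside asymmetry parameters.
#'
#' @param aligned an `aligned_contour`.
#' @param separation angular separation from the SP in degrees, strictly
#'   between 0 and 180 (default 70).
#' @return list with `sp_index` (grid index of offset 0), `brsp_angle`
#'   (= `separation`), `blsp_angle` (= `-separation`) and `separation`.
#' @export
locate_backside_anchors <- function(aligned, separation = 70) {
  if (!is.numeric(separation) || length(separation) != 1 ||
      separation <= 0 || separation >= 180)
    validation_error("separation must lie strictly between 0 and 180 degrees")
  separation <- round(separation)
  list(sp_index = match(0, aligned$theta),
       brsp_angle = separation, blsp_angle = -separation,
       separation = separation)
}

#' Approximate the vertebral-body line of a slice
#'
#' The vertebral-body center is placed on the vertical SP-centroid axis, at
#' `sp_offset` mm anterior of the SP surface point (an assumed spinous
#' process length; vertebral-body anatomy itself is not modeled). The VB
#' line is the horizontal line through that center in the aligned frame.
#'
#' @param aligned an `aligned_contour`.
#' @param sp_offset assumed spinous-process length in mm (> 0, default 40).
#' @return list with `vb_center` (c(x, y) in the aligned, centroid-origin
#'   frame), `direction` (unit vector, horizontal), `sp_offset` and
#'   `vb_height` (y-coordinate of the VB line).
#' @export
estimate_vb_line <- function(aligned, sp_offset = 40) {
  if (!is.numeric(sp_offset) || length(sp_offset) != 1 || sp_offset <= 0)
    validation_error("sp_offset must be a positive length in mm")
  r0 <- grid_r(aligned, 0)        # SP radius: SP point is at (0, -r0)
  y <- sp_offset - r0
  inside <- if (y < 0) -y < r0 else y < grid_r(aligned, 180)
  if (!inside)
    validation_error(sprintf(
      "vertebral-body center at y = %.1f mm falls outside the contour", y))
  list(vb_center = c(0, y), direction = c(1, 0),
       sp_offset = sp_offset, vb_height = y)
}
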