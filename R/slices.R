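# Slice extraction: vertebral level heights from the three marked landmarks,
# mesh/plane intersection, and angular-mask removal of arm fragments.

#' Interpolate vertebral level heights from C7, T8 and L5 landmarks
#'
#' Only three levels are marked on a scan (C7 at the top of the analyzed
#' region, T8 in the middle, L5 at the bottom); the remaining levels are
#' placed by equal spacing within each span: C7-T8 is divided into 8 equal
#' intervals (C7, T1..T8) and T8-L5 into 9 equal intervals (T9..T12, L1..L5).
#'
#' @param landmarks named numeric vector or list with elements `c7`, `t8`,
#'   `l5`: heights along the vertical body axis in mm, superior largest.
#' @return data frame with columns `level` (factor ordered C7..L5) and
#'   `height` (mm, strictly decreasing).
#' @export
interpolate_levels <- function(landmarks) {
  lm <- as.list(landmarks)
  need <- c("c7", "t8", "l5")
  if (!all(need %in% tolower(names(lm))))
    validation_error("landmarks must provide c7, t8 and l5 heights")
  names(lm) <- tolower(names(lm))
  c7 <- as.numeric(lm$c7); t8 <- as.numeric(lm$t8); l5 <- as.numeric(lm$l5)
  if (!(c7 > t8 && t8 > l5))
    validation_error("landmark heights must satisfy c7 > t8 > l5")
  upper <- c7 - (0:8) * (c7 - t8) / 8        # C7, T1..T8
  lower <- t8 - (1:9) * (t8 - l5) / 9        # T9..T12, L1..L5
  data.frame(level = factor(LEVEL_LABELS, levels = LEVEL_LABELS),
             height = c(upper, lower))
}

#' Extract the transverse contour of a mesh at a given height
#'
#' Intersects the mesh with the horizontal plane `z = height` and chains the
#' resulting segments into closed loops. When several closed loops are found
#' (torso plus arms at lower levels), the loop with the largest enclosed
#' area is kept. The returned contour is counterclockwise viewed from
#' superior.
#'
#' @param mesh a [torso_mesh].
#' @param height cutting height (mm) along the vertical axis.
#' @param level optional level label attached to the result.
#' @return a [raw_contour] of the (x, y) intersection loop.
#' @export
extract_slice <- function(mesh, height, level = NA_character_) {
  v <- mesh$vertices; f <- mesh$faces
  zr <- range(v[, 3])
  if (height < zr[1] || height > zr[2])
    abort(sprintf("slice height %.2f outside mesh vertical extent [%.2f, %.2f]",
                  height, zr[1], zr[2]), "torsometry_empty_slice_error")
  eps <- max(1e-9, (zr[2] - zr[1]) * 1e-9)
  s <- v[, 3] - height
  # nudge the plane off any vertex it passes exactly through
  tries <- 0
  while (any(abs(s) < eps) && tries < 5) {
    height <- height + 37 * eps
    s <- v[, 3] - height
    tries <- tries + 1
  }
  if (any(abs(s) < eps))
    topology_error("could not place cutting plane away from mesh vertices")

  s1 <- s[f[, 1]]; s2 <- s[f[, 2]]; s3 <- s[f[, 3]]
  crossing <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossing))
    abort("cutting plane does not intersect the mesh surface",
          "torsometry_empty_slice_error")
  fc <- f[crossing, , drop = FALSE]
  sc <- cbind(s1, s2, s3)[crossing, , drop = FALSE]

  # the 'lone' vertex is on the minority side; its two edges cross the plane
  pos <- sc > 0
  npos <- rowSums(pos)
  lone <- integer(nrow(fc))
  lone[npos == 1] <- max.col(pos[npos == 1, , drop = FALSE], ties.method = "first")
  lone[npos == 2] <- max.col(!pos[npos == 2, , drop = FALSE], ties.method = "first")
  other1 <- (lone %% 3) + 1L
  other2 <- (other1 %% 3) + 1L
  idx <- function(col) fc[cbind(seq_len(nrow(fc)), col)]
  ia <- idx(lone); ib <- idx(other1); ic <- idx(other2)
  seg_pt <- function(i, j) {
    t <- s[i] / (s[i] - s[j])
    v[i, 1:2, drop = FALSE] + t * (v[j, 1:2, drop = FALSE] - v[i, 1:2, drop = FALSE])
  }
  p1 <- seg_pt(ia, ib)
  p2 <- seg_pt(ia, ic)

  loops <- chain_segments(p1, p2, tol = max(1e-7, diff(zr) * 1e-8))
  if (length(loops$closed) == 0) {
    topology_error(sprintf(
      "slice at height %.2f produced no closed loop (%d open chains); mesh may have holes",
      height, length(loops$open)))
  }
  areas <- vapply(loops$closed, function(L) abs(shoelace_area(L)), 0)
  raw_contour(loops$closed[[which.max(areas)]], level = level, check_simple = FALSE)
}

# Chain unordered segments (p1[i,] -- p2[i,]) into loops by endpoint matching.
#' @keywords internal
#' @noRd
chain_segments <- function(p1, p2, tol = 1e-7) {
  n <- nrow(p1)
  key <- function(p) paste(round(p[, 1] / tol), round(p[, 2] / tol))
  k1 <- key(p1); k2 <- key(p2)
  # adjacency: each endpoint key maps to the segments touching it
  ends <- data.frame(seg = rep(seq_len(n), 2), side = rep(1:2, each = n),
                     key = c(k1, k2), stringsAsFactors = FALSE)
  by_key <- split(seq_len(2 * n), ends$key)
  used <- logical(n)
  closed <- list(); open <- list()
  for (start in seq_len(n)) {
    if (used[start]) next
    used[start] <- TRUE
    pts <- rbind(p1[start, ], p2[start, ])
    start_key <- k1[start]
    cur_key <- k2[start]
    repeat {
      cand <- by_key[[cur_key]]
      seg_ids <- ends$seg[cand]
      nxt <- cand[!used[seg_ids]][1]
      if (is.na(nxt)) break
      sid <- ends$seg[nxt]; side <- ends$side[nxt]
      used[sid] <- TRUE
      if (side == 1) { pts <- rbind(pts, p2[sid, ]); cur_key <- k2[sid] }
      else           { pts <- rbind(pts, p1[sid, ]); cur_key <- k1[sid] }
      if (cur_key == start_key) break
    }
    if (cur_key == start_key && nrow(pts) >= 4) {
      closed[[length(closed) + 1]] <- pts[-nrow(pts), , drop = FALSE]
    } else {
      open[[length(open) + 1]] <- pts
    }
  }
  list(closed = closed, open = open)
}

#' Remove angular sectors (arm fragments) from a contour
#'
#' At lower thoracic levels the scanned arms can intrude into the transverse
#' plane. Instead of manual editing, configured angular masks remove all
#' points whose polar angle about the contour centroid falls inside a mask;
#' each gap is bridged with points interpolated linearly across the chord so
#' downstream angular resampling stays defined.
#'
#' Angles are geometric degrees in the raw frame: 0 = +x, 90 = +y
#' (anterior), -90 = posterior.
#'
#' @param contour a [raw_contour].
#' @param masks list of length-2 numeric vectors `c(from, to)` in degrees,
#'   swept counterclockwise from `from` to `to` (so `c(170, -170)` masks a
#'   20-degree sector through the wrap).
#' @return a [raw_contour] with masked sectors replaced by chords; a
#'   recorded warning (see [torso_warnings]) notes each interpolated sector.
#' @export
exclude_sector <- function(contour, masks = list()) {
  if (length(masks) == 0) return(contour)
  ctr <- compute_centroid(contour)
  ang <- atan2(contour[, 2] - ctr[2], contour[, 1] - ctr[1]) * 180 / pi
  widths <- vapply(masks, function(m) wrap360(m[2] - m[1]), 0)
  if (sum(widths) >= 180)
    validation_error("angular masks cover >= 180 degrees; contour not analyzable")
  in_mask <- rep(FALSE, nrow(contour))
  for (m in masks) {
    w <- wrap360(m[2] - m[1])
    off <- wrap360(ang - m[1])
    in_mask <- in_mask | (off <= w)
  }
  if (!any(in_mask)) return(contour)
  n <- nrow(contour)
  keep <- which(!in_mask)
  if (length(keep) < 3) validation_error("masking removed almost the whole contour")
  # walk kept points in loop order; bridge every gap where points were removed
  pts_out <- list()
  gap_after <- which(diff(c(keep, keep[1] + n)) > 1)
  mean_step <- 360 / n  # typical angular spacing, for chord point count
  for (i in seq_along(keep)) {
    pts_out[[length(pts_out) + 1]] <- contour[keep[i], , drop = FALSE]
    if (i %in% gap_after) {
      a <- contour[keep[i], ]
      b <- contour[keep[ifelse(i == length(keep), 1, i + 1)], ]
      ang_a <- atan2(a[2] - ctr[2], a[1] - ctr[1]) * 180 / pi
      ang_b <- atan2(b[2] - ctr[2], b[1] - ctr[1]) * 180 / pi
      gap <- wrap360(ang_b - ang_a)
      k <- max(0L, ceiling(gap / mean_step) - 1L)
      if (k > 0) {
        t <- seq_len(k) / (k + 1)
        pts_out[[length(pts_out) + 1]] <-
          cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
      }
    }
  }
  out <- raw_contour(do.call(rbind, pts_out), level = attr(contour, "level"),
                     check_simple = FALSE)
  out <- carry_warnings(out, contour)
  add_warning(out, sprintf(
    "masked %d point(s) in %d sector(s); gaps bridged by linear interpolation",
    sum(in_mask), length(gap_after)))
}
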