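# Raw transverse contours: an ordered closed 2D point loop at one vertebral
# level, in mm, counterclockwise when viewed from superior (anterior = +y).

LEVEL_LABELS <- c("C7", paste0("T", 1:12), paste0("L", 1:5))

#' Vertebral level labels from C7 to L5
#'
#' @return character vector of the 18 analyzed vertebral levels, superior to
#'   inferior: `"C7"`, `"T1"` ... `"T12"`, `"L1"` ... `"L5"`.
#' @export
vertebral_levels <- function() LEVEL_LABELS

#' @keywords internal
#' @noRd
level_index <- function(level) {
  i <- match(level, LEVEL_LABELS)
  if (anyNA(i)) validation_error(paste0("unknown vertebral level: ",
                                        paste(level[is.na(i)], collapse = ", ")))
  i
}

#' Construct a raw transverse contour
#'
#' A raw contour is the ordered, closed boundary of one transverse torso
#' cross-section. Points are stored counterclockwise viewed from superior,
#' with the anterior direction at +y. Consecutive duplicate points are
#' dropped; orientation is normalized to counterclockwise.
#'
#' @param points two-column numeric matrix (or data frame) of x, y
#'   coordinates in mm, in loop order.
#' @param level vertebral level label (`"C7"`, `"T1"` ... `"L5"`) or `NA`.
#' @param min_points minimum number of distinct points required (default 30;
#'   coarser loops carry too little shape information for the 1-degree
#'   angular analysis).
#' @param check_simple if `TRUE` (default for loops up to 2000 points),
#'   verify the loop does not self-intersect.
#' @return an object of class `raw_contour`: the point matrix with
#'   attributes `level` and `closed`.
#' @export
raw_contour <- function(points, level = NA_character_, min_points = 30,
                        check_simple = NULL) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2)
    validation_error("contour points must be a two-column numeric matrix")
  if (anyNA(pts) || any(!is.finite(pts)))
    validation_error("contour points must be finite")
  # drop consecutive duplicates (including the closing repeat of point 1)
  n <- nrow(pts)
  if (n > 1) {
    d <- rowSums(abs(pts - pts[c(n, seq_len(n - 1)), , drop = FALSE]))
    if (!any(d > 0)) validation_error("degenerate contour: all points identical")
    pts <- pts[d > 0, , drop = FALSE]
  }
  if (nrow(pts) < min_points)
    validation_error(sprintf("contour needs >= %d distinct points, got %d",
                             min_points, nrow(pts)))
  if (!is.na(level) && !(level %in% LEVEL_LABELS))
    validation_error(paste0("unknown vertebral level: ", level))
  a <- shoelace_area(pts)
  if (abs(a) < .Machine$double.eps * 100)
    validation_error("degenerate contour: zero enclosed area")
  if (a < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  if (is.null(check_simple)) check_simple <- nrow(pts) <= 2000
  if (check_simple && !is_simple_loop(pts))
    validation_error("contour is self-intersecting")
  structure(pts, class = "raw_contour", level = level, closed = TRUE,
            dimnames = list(NULL, c("x", "y")))
}

#' @export
print.raw_contour <- function(x, ...) {
  cat(sprintf("raw_contour: %d points, level %s, area %.1f mm^2\n",
              nrow(x), attr(x, "level"), abs(shoelace_area(x))))
  invisible(x)
}

# All-pairs segment intersection test (vectorized; intended for loops of at
# most a few thousand points). Shared endpoints of adjacent edges are allowed.
#' @keywords internal
#' @noRd
is_simple_loop <- function(pts) {
  n <- nrow(pts)
  a <- pts
  b <- pts[c(2:n, 1), , drop = FALSE]
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j) {
    sep <- (j - i) %% n
    sep > 1 & sep < n - 1
  }), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  if (nrow(idx) == 0) return(TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  p <- a[i, , drop = FALSE]; r <- b[i, , drop = FALSE] - p
  q <- a[j, , drop = FALSE]; s <- b[j, , drop = FALSE] - q
  rxs <- r[, 1] * s[, 2] - r[, 2] * s[, 1]
  qp <- q - p
  qpxr <- qp[, 1] * r[, 2] - qp[, 2] * r[, 1]
  qpxs <- qp[, 1] * s[, 2] - qp[, 2] * s[, 1]
  ok <- abs(rxs) > .Machine$double.eps
  t <- ifelse(ok, qpxs / rxs, NA_real_)
  u <- ifelse(ok, qpxr / rxs, NA_real_)
  hit <- ok & t > 0 & t < 1 & u > 0 & u < 1
  !any(hit, na.rm = TRUE)
}

#' Read contours from a CSV or JSON file
#'
#' The CSV layout has columns `level_label`, `x`, `y` with one row per
#' contour point (all levels of one torso in a single file, points in loop
#' order within a level). The JSON layout is an object mapping level labels
#' to arrays of `[x, y]` pairs. All lengths are mm.
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @return named list of [raw_contour] objects, ordered superior to inferior.
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("level_label", "x", "y")
    if (!all(need %in% names(df)))
      format_error("contour CSV must have columns level_label,x,y")
    split_pts <- split(df[, c("x", "y")], df$level_label)
  } else if (ext == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    split_pts <- lapply(raw, function(m) {
      m <- as.matrix(m)
      colnames(m) <- c("x", "y")
      as.data.frame(m)
    })
  } else {
    format_error("unsupported contour file format (use .csv or .json)")
  }
  labs <- intersect(LEVEL_LABELS, names(split_pts))
  if (length(labs) == 0) format_error("no recognizable vertebral levels in file")
  out <- lapply(labs, function(l) raw_contour(as.matrix(split_pts[[l]]), level = l))
  names(out) <- labs
  out
}

#' Write contours to CSV or JSON
#'
#' @param contours named list of [raw_contour] objects (names are level labels).
#' @param path output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  labs <- names(contours)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- do.call(rbind, lapply(labs, function(l) {
      data.frame(level_label = l, x = contours[[l]][, 1], y = contours[[l]][, 2])
    }))
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext == "json") {
    obj <- lapply(contours, function(ct) unname(apply(unclass(ct), 1, c, simplify = FALSE)))
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  } else {
    format_error("unsupported contour file format (use .csv or .json)")
  }
  invisible(path)
}
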