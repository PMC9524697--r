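# Internal helpers shared across modules.

#' Wrap angles in degrees to the half-open interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped.
#' @keywords internal
#' @noRd
wrap180 <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Wrap angles to [0, 360)
#' @keywords internal
#' @noRd
wrap360 <- function(x) x %% 360

#' Smallest absolute angular difference a - b in degrees, in (-180, 180]
#' @keywords internal
#' @noRd
ang_diff <- function(a, b) wrap180(a - b)

#' Collect the warnings recorded on an object
#'
#' Pipeline stages record non-fatal diagnostics (low-confidence landmark
#' detection, masked sectors, interpolated gaps) as a character vector in the
#' `"torso_warnings"` attribute rather than raising R conditions, so that a
#' batch run over 18 vertebral levels stays quiet but fully auditable.
#'
#' @param x any object produced by torsometry.
#' @return character vector of recorded warnings (possibly empty).
#' @export
torso_warnings <- function(x) {
  w <- attr(x, "torso_warnings")
  if (is.null(w)) character(0) else w
}

#' @keywords internal
#' @noRd
add_warning <- function(x, msg) {
  attr(x, "torso_warnings") <- c(torso_warnings(x), msg)
  x
}

#' @keywords internal
#' @noRd
carry_warnings <- function(x, from) {
  w <- torso_warnings(from)
  if (length(w)) attr(x, "torso_warnings") <- c(torso_warnings(x), w)
  x
}

# stop() with a classed condition so callers can distinguish validation
# errors (bad inputs/parameters) from format and topology errors.
#' @keywords internal
#' @noRd
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "torsometry_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

validation_error <- function(msg) abort(msg, "torsometry_validation_error")
format_error     <- function(msg) abort(msg, "torsometry_format_error")
geometry_error   <- function(msg) abort(msg, "torsometry_geometry_error")
topology_error   <- function(msg) abort(msg, "torsometry_topology_error")
run_error        <- function(msg) abort(msg, "torsometry_run_error")

#' Ray-crossing point-in-polygon test
#' @param pt length-2 numeric.
#' @param poly two-column matrix of polygon vertices (closed implicitly).
#' @keywords internal
#' @noRd
point_in_polygon <- function(pt, poly) {
  x <- poly[, 1] - pt[1]
  y <- poly[, 2] - pt[2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  xj <- x[j]; yj <- y[j]
  cross <- (y > 0) != (yj > 0)
  if (!any(cross)) return(FALSE)
  # x-coordinate where each crossing edge meets the horizontal ray
  xi <- x[cross] - y[cross] * (xj[cross] - x[cross]) / (yj[cross] - y[cross])
  sum(xi > 0) %% 2 == 1
}

#' Signed polygon area (shoelace)
#' @keywords internal
#' @noRd
shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}
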