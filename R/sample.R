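#' Construct a circular sample
#'
#' Normalizes a vector of angles into the canonical internal representation:
#' radians on \eqn{[0, 2\pi)}, original order preserved. Degrees are accepted
#' at this boundary only; all downstream computation is in radians.
#'
#' @param angles numeric vector of angles, at least one, all finite.
#' @param units units of `angles`: `"degrees"` (common in field data) or
#'   `"radians"`.
#' @param grouping_m optional positive integer: the number of evenly spaced
#'   values the data are restricted to (e.g. 36 for measurements rounded to
#'   the nearest 10 degrees). Set automatically by [circ_group()].
#'
#' @return A numeric vector of class `"circ_sample"`: angles in radians in
#'   \eqn{[0, 2\pi)}, with attributes `units_original` and (optionally)
#'   `grouping_m`.
#' @examples
#' circ_sample(c(370, -90), units = "degrees")
#' circ_sample(pigeon_bearings)
#' @export
circ_sample <- function(angles, units = c("degrees", "radians"),
                        grouping_m = NULL) {
  units <- match.arg(units)
  if (length(angles) == 0L) stop("empty sample")
  angles <- as.numeric(angles)
  bad <- which(!is.finite(angles))
  if (length(bad) > 0L)
    stop("non-finite angle at index ", bad[1L])
  theta <- if (units == "degrees") angles * pi / 180 else angles
  theta <- wrap_angle(theta)
  if (!is.null(grouping_m)) {
    grouping_m <- as.integer(grouping_m)
    stopifnot(grouping_m >= 2L)
  }
  structure(theta, class = "circ_sample",
            units_original = units, grouping_m = grouping_m)
}

#' Coerce to a circular sample
#'
#' Bare numeric vectors are interpreted as radians and wrapped into
#' \eqn{[0, 2\pi)}; `circ_sample` objects pass through unchanged.
#'
#' @param x numeric vector (radians) or a `circ_sample`.
#' @return A `circ_sample`.
#' @export
as_circ_sample <- function(x) {
  if (inherits(x, "circ_sample")) return(x)
  circ_sample(x, units = "radians")
}

# reduce any finite angle (radians) into [0, 2*pi)
wrap_angle <- function(theta) {
  out <- theta %% (2 * pi)
  # x %% 2*pi can return 2*pi itself for tiny negative x; fold it back
  out[out >= 2 * pi] <- 0
  out
}

#' @export
print.circ_sample <- function(x, ...) {
  m <- attr(x, "grouping_m")
  cat(sprintf("Circular sample: n = %d, units recorded as %s%s\n",
              length(x), attr(x, "units_original"),
              if (is.null(m)) "" else sprintf(", grouped to m = %d values", m)))
  print(as.numeric(x), ...)
  invisible(x)
}

#' Circular spacings (arc lengths between adjacent points)
#'
#' For a sample of \eqn{n \ge 2} angles, returns the \eqn{n} arc lengths
#' \eqn{T_i} between circularly adjacent points of the sorted sample, with
#' the wrap-around spacing \eqn{T_n = 2\pi - \phi_{(n)} + \phi_{(1)}}.
#' Tied angles (as produced by grouping) give zero spacings, which are legal
#' and are precisely what destabilizes spacing-based tests on grouped data.
#' The spacings always sum to \eqn{2\pi}.
#'
#' @param x a [circ_sample()] or numeric vector of radians.
#' @return numeric vector of n non-negative spacings summing to \eqn{2\pi}.
#' @examples
#' circ_spacings(circ_sample(c(0, 90, 180, 270), units = "degrees"))
#' @export
circ_spacings <- function(x) {
  x <- as_circ_sample(x)
  n <- length(x)
  if (n < 2L) stop("need at least two points")
  s <- sort(as.numeric(x))
  c(diff(s), 2 * pi - s[n] + s[1L])
}

#' Group (round) a circular sample onto m evenly spaced values
#'
#' Replaces each angle with the nearest multiple of \eqn{2\pi/m}, emulating
#' measurement rounded to a fixed angular resolution (m = 36 corresponds to
#' the nearest 10 degrees). Angles within half a bin below \eqn{2\pi} wrap to
#' 0. Ties at bin midpoints round half-up, toward the larger multiple; this
#' convention only matters on a measure-zero set of continuous inputs.
#'
#' @param x a [circ_sample()] or numeric vector of radians.
#' @param m positive integer \eqn{\ge 2}, number of values around the circle.
#' @return A `circ_sample` with `grouping_m = m`. Idempotent:
#'   `circ_group(circ_group(x, m), m)` equals `circ_group(x, m)`.
#' @examples
#' circ_group(circ_sample(c(14.9, 355.1), units = "degrees"), 36)
#' @export
circ_group <- function(x, m) {
  x <- as_circ_sample(x)
  m <- as.integer(m)
  if (is.na(m) || m < 2L) stop("m must be an integer >= 2")
  w <- 2 * pi / m
  # half-up rounding; the 1e-9 guard keeps exact midpoints (e.g. 15 degrees
  # with m = 36) on the upper side despite degrees->radians roundoff
  idx <- floor(as.numeric(x) / w + 0.5 + 1e-9) %% m
  structure(idx * w, class = "circ_sample",
            units_original = attr(x, "units_original"),
            grouping_m = m)
}

#' Rotate a circular sample by a fixed offset
#'
#' @param x a [circ_sample()] or numeric vector of radians.
#' @param delta rotation in radians.
#' @return the rotated `circ_sample` (grouping metadata is dropped, since an
#'   arbitrary rotation moves points off the grouping grid).
#' @export
circ_rotate <- function(x, delta) {
  x <- as_circ_sample(x)
  structure(wrap_angle(as.numeric(x) + delta), class = "circ_sample",
            units_original = attr(x, "units_original"), grouping_m = NULL)
}

#' Vanishing bearings of 13 homing pigeons
#'
#' A classic small directional dataset: compass bearings (degrees from
#' North) at which 13 released homing pigeons vanished from sight. The
#' values appear to be rounded to the nearest 5 degrees and look bimodal,
#' clustering near North and South; three birds share the bearing 350.
#' Used as the worked example throughout the package.
#'
#' @format numeric vector of 13 bearings in degrees.
#' @export
pigeon_bearings <- c(20, 135, 145, 165, 170, 200, 300, 325, 335,
                     350, 350, 350, 355)

#' Read angles from a plain-text or CSV file
#'
#' Accepts either one angle per line (possibly with `#` comment lines) or a
#' CSV with a named column.
#'
#' @param file path to the file.
#' @param units `"degrees"` (default) or `"radians"`.
#' @param column optional column name; if `NULL` the file is read as one
#'   bare angle per line.
#' @return A [circ_sample()].
#' @export
read_angles <- function(file, units = c("degrees", "radians"), column = NULL) {
  units <- match.arg(units)
  if (!file.exists(file)) stop("cannot read file: ", file)
  values <- if (is.null(column)) {
    scan(file, what = numeric(), comment.char = "#", quiet = TRUE)
  } else {
    df <- utils::read.csv(file, comment.char = "#")
    if (!column %in% names(df)) stop("no column named '", column, "' in ", file)
    df[[column]]
  }
  circ_sample(values, units = units)
}

#' Write angles to a plain-text file
#'
#' Mirrors [read_angles()]: one angle per line, with a comment header
#' recording the units.
#'
#' @param x a [circ_sample()] or numeric vector of radians.
#' @param file output path.
#' @param units output units, `"degrees"` or `"radians"`.
#' @export
write_angles <- function(x, file, units = c("degrees", "radians")) {
  units <- match.arg(units)
  x <- as_circ_sample(x)
  values <- if (units == "degrees") as.numeric(x) * 180 / pi else as.numeric(x)
  writeLines(c(sprintf("# angles in %s", units),
               format(values, digits = 15, trim = TRUE)), con = file)
  invisible(file)
}
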