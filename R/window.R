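#' Rectangular observation window
#'
#' Axis-aligned rectangle, in micrometres, standing in for the imaged tissue
#' section. All spatial statistics in this package (Ripley's K, quadrat
#' tessellation, nearest-neighbour analysis) are defined relative to such a
#' window; irregular tissue masks are approximated by the bounding rectangle
#' of the cell coordinates.
#'
#' @param x_min,y_min,x_max,y_max Window corners in micrometres. Must satisfy
#'   `x_max > x_min` and `y_max > y_min`.
#' @return An object of class `tissue_window` with fields `x_min`, `y_min`,
#'   `x_max`, `y_max`.
#' @examples
#' w <- tissue_window(0, 0, 1000, 1000)
#' window_area(w) # 1e6 um^2 = 1 mm^2
#' @export
tissue_window <- function(x_min, y_min, x_max, y_max) {
  vals <- c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
  if (!all(is.finite(vals))) {
    stop("window corners must be finite numbers", call. = FALSE)
  }
  if (x_max <= x_min || y_max <= y_min) {
    stop("degenerate window: need x_max > x_min and y_max > y_min",
         call. = FALSE)
  }
  structure(list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max),
            class = "tissue_window")
}

#' @export
print.tissue_window <- function(x, ...) {
  cat(sprintf("tissue window [%g, %g] x [%g, %g] um, area %g um^2\n",
              x$x_min, x$x_max, x$y_min, x$y_max, window_area(x)))
  invisible(x)
}

#' @rdname tissue_window
#' @param window A `tissue_window`.
#' @export
window_area <- function(window) {
  stopifnot(inherits(window, "tissue_window"))
  (window$x_max - window$x_min) * (window$y_max - window$y_min)
}

#' Side lengths of a window
#'
#' @param window A `tissue_window`.
#' @return Numeric vector `c(width, height)` in micrometres.
#' @export
window_sides <- function(window) {
  stopifnot(inherits(window, "tissue_window"))
  c(window$x_max - window$x_min, window$y_max - window$y_min)
}

#' Bounding rectangle of a set of points
#'
#' Used when a cell table arrives without a declared window: the observation
#' region is approximated by the smallest axis-aligned rectangle containing
#' all cells.
#'
#' @param x,y Coordinates in micrometres.
#' @return A `tissue_window`.
#' @export
bounding_window <- function(x, y) {
  if (length(x) == 0) stop("no points to bound", call. = FALSE)
  tissue_window(min(x), min(y), max(x), max(y))
}

# TRUE for points inside the (closed) window
points_in_window <- function(x, y, window) {
  x >= window$x_min & x <= window$x_max &
    y >= window$y_min & y <= window$y_max
}

assert_points_in_window <- function(x, y, window, what = "points") {
  out <- !points_in_window(x, y, window)
  if (any(out)) {
    stop(sprintf("%d %s lie outside the window (first at index %d)",
                 sum(out), what, which(out)[1]), call. = FALSE)
  }
  invisible(TRUE)
}
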