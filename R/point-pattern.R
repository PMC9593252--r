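#' Rectangular observation window
#'
#' Axis-aligned rectangle in nm, the observation window for all point
#' patterns. Stored as a named numeric vector `c(xmin, xmax, ymin, ymax)`.
#'
#' @param xmin,xmax,ymin,ymax window limits in nm.
#' @return A named numeric vector of class `"ncd_window"`.
#' @examples
#' owin_rect(0, 10000, 0, 10000)  # 10 x 10 um
#' @export
owin_rect <- function(xmin, xmax, ymin, ymax) {
  w <- c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
  if (any(!is.finite(w))) stop("window limits must be finite")
  if (xmax <= xmin || ymax <= ymin) stop("window must have positive extent")
  class(w) <- "ncd_window"
  w
}

#' @rdname owin_rect
#' @param window an `ncd_window` (or numeric vector of length 4).
#' @export
window_area <- function(window) {
  unname((window[["xmax"]] - window[["xmin"]]) *
         (window[["ymax"]] - window[["ymin"]]))
}

as_window <- function(window) {
  if (inherits(window, "ncd_window")) return(window)
  if (is.numeric(window) && length(window) == 4L)
    return(owin_rect(window[[1]], window[[2]], window[[3]], window[[4]]))
  stop("window must be an ncd_window or numeric c(xmin, xmax, ymin, ymax)")
}

#' Planar point pattern of molecule coordinates
#'
#' A set of 2D molecule positions (nm) in a rectangular observation window,
#' the basic container consumed by the pair-correlation, colocalization and
#' domain analyses. Density is defined as count / window area.
#'
#' @param x,y numeric coordinates in nm.
#' @param window observation window (see [owin_rect()]). If `NULL`, the
#'   bounding box of the points is used.
#' @param label optional channel / species label.
#' @param t_start,t_end optional start/end time in seconds, used for
#'   fixed-duration acquisition windows.
#' @return An object of class `"point_pattern"` with elements `x`, `y`,
#'   `window`, `label`, `t_start`, `t_end`.
#' @seealso [pp_density()], [crop_roi()], [pcf()]
#' @export
point_pattern <- function(x, y, window = NULL, label = NULL,
                          t_start = NULL, t_end = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite")
  if (is.null(window)) {
    window <- if (length(x)) owin_rect(min(x), max(x) + 1e-9,
                                       min(y), max(y) + 1e-9)
              else owin_rect(0, 1, 0, 1)
  } else window <- as_window(window)
  tol <- 1e-9
  if (length(x) && (any(x < window[["xmin"]] - tol | x > window[["xmax"]] + tol) ||
                    any(y < window[["ymin"]] - tol | y > window[["ymax"]] + tol)))
    stop("all points must lie inside the observation window")
  structure(list(x = x, y = y, window = window, label = label,
                 t_start = t_start, t_end = t_end),
            class = "point_pattern")
}

#' @rdname point_pattern
#' @param pattern a `point_pattern`.
#' @export
npoints <- function(pattern) length(pattern$x)

#' Molecular density of a point pattern
#'
#' @param pattern a [point_pattern()].
#' @param units `"um2"` (molecules per square micron, the conventional SMLM
#'   unit) or `"nm2"`.
#' @return Density as count / window area.
#' @export
pp_density <- function(pattern, units = c("um2", "nm2")) {
  units <- match.arg(units)
  d <- npoints(pattern) / window_area(pattern$window)  # per nm^2
  if (units == "um2") d * 1e6 else d
}

#' @export
print.point_pattern <- function(x, ...) {
  cat("Planar point pattern:", npoints(x), "points\n")
  if (!is.null(x$label)) cat("  label:", x$label, "\n")
  w <- x$window
  cat(sprintf("  window: [%g, %g] x [%g, %g] nm (%.3g um^2)\n",
              w[["xmin"]], w[["xmax"]], w[["ymin"]], w[["ymax"]],
              window_area(w) / 1e6))
  cat(sprintf("  density: %.4g molecules/um^2\n", pp_density(x)))
  if (!is.null(x$t_start))
    cat(sprintf("  time: %g - %g s\n", x$t_start,
                if (is.null(x$t_end)) NA_real_ else x$t_end))
  invisible(x)
}

#' @export
plot.point_pattern <- function(x, pch = 16, cex = 0.4, asp = 1, ...) {
  w <- x$window
  plot(x$x, x$y, pch = pch, cex = cex, asp = asp,
       xlim = c(w[["xmin"]], w[["xmax"]]), ylim = c(w[["ymin"]], w[["ymax"]]),
       xlab = "x [nm]", ylab = "y [nm]",
       main = if (is.null(x$label)) "" else x$label, ...)
  rect(w[["xmin"]], w[["ymin"]], w[["xmax"]], w[["ymax"]], border = "grey40")
  invisible(x)
}

same_window <- function(a, b, tol = 1e-6) {
  all(abs(unclass(a$window) - unclass(b$window)) < tol)
}

#' Crop a point pattern to a rectangular region of interest
#'
#' Retains the points falling in `rect` and replaces the observation window
#' by `rect`. Used to restrict per-cluster analyses to a 1.5 x 1.5 um region
#' of interest. Points exactly on the ROI boundary are retained.
#'
#' @param pattern a [point_pattern()].
#' @param rect the ROI, an [owin_rect()] (nm) intersecting the window.
#' @return The cropped `point_pattern` with `rect` as its window.
#' @export
crop_roi <- function(pattern, rect) {
  rect <- as_window(rect)
  w <- pattern$window
  if (rect[["xmin"]] >= w[["xmax"]] || rect[["xmax"]] <= w[["xmin"]] ||
      rect[["ymin"]] >= w[["ymax"]] || rect[["ymax"]] <= w[["ymin"]])
    stop("ROI does not intersect the observation window")
  keep <- pattern$x >= rect[["xmin"]] & pattern$x <= rect[["xmax"]] &
          pattern$y >= rect[["ymin"]] & pattern$y <= rect[["ymax"]]
  point_pattern(pattern$x[keep], pattern$y[keep], window = rect,
                label = pattern$label, t_start = pattern$t_start,
                t_end = pattern$t_end)
}
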