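#' Screen and viewing geometry
#'
#' Describes the stimulus monitor and viewing distance used to convert pixel
#' coordinates into degrees of visual angle. Defaults correspond to a 24-inch
#' 16:10 panel at 1920 x 1200 viewed from 94 cm behind a chin rest.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param width_mm,height_mm Physical panel size in millimetres.
#' @param distance_mm Viewing distance in millimetres (default 940).
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' px_to_deg(c(960, 600), geom)  # screen centre -> (0, 0)
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1200,
                            width_mm = 518.4, height_mm = 324,
                            distance_mm = 940) {
  vals <- c(width_px, height_px, width_mm, height_mm, distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry dimensions must be positive and finite", call. = FALSE)
  structure(list(width_px = width_px, height_px = height_px,
                 width_mm = width_mm, height_mm = height_mm,
                 distance_mm = distance_mm),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("Screen geometry: %d x %d px (%.1f x %.1f mm) at %.0f mm\n",
              x$width_px, x$height_px, x$width_mm, x$height_mm, x$distance_mm))
  invisible(x)
}

#' Convert pixel coordinates to degrees of visual angle
#'
#' Maps screen pixel positions to horizontal/vertical visual angle relative to
#' the screen centre, per axis, using `atan(physical offset / viewing
#' distance)`. The mapping is odd: `px_to_deg(-p) = -px_to_deg(p)` about the
#' centre. Points outside the panel (e.g. the partner's face above the screen
#' top edge) are valid; the angular mapping simply extrapolates.
#'
#' @param xy Numeric vector `c(x, y)` or a two-column matrix of pixel
#'   coordinates (origin top-left, y increasing downward).
#' @param geometry A [screen_geometry()].
#' @return Matrix (or length-2 vector) of angles in degrees, same shape as
#'   input.
#' @export
px_to_deg <- function(xy, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "screen_geometry"))
  m <- if (is.null(dim(xy))) matrix(xy, ncol = 2) else as.matrix(xy)
  if (ncol(m) != 2 || any(!is.finite(m)))
    stop("'xy' must be finite x,y coordinates", call. = FALSE)
  sx <- geometry$width_mm / geometry$width_px
  sy <- geometry$height_mm / geometry$height_px
  dx_mm <- (m[, 1] - geometry$width_px / 2) * sx
  dy_mm <- (m[, 2] - geometry$height_px / 2) * sy
  out <- cbind(atan2(dx_mm, geometry$distance_mm),
               atan2(dy_mm, geometry$distance_mm)) * 180 / pi
  colnames(out) <- c("deg_x", "deg_y")
  if (is.null(dim(xy))) out[1, ] else out
}

# Inverse of px_to_deg, used by the synthetic stream builder so saccade
# velocity profiles can be specified in angular units.
deg_to_px <- function(deg, geometry = screen_geometry()) {
  m <- if (is.null(dim(deg))) matrix(deg, ncol = 2) else as.matrix(deg)
  sx <- geometry$width_mm / geometry$width_px
  sy <- geometry$height_mm / geometry$height_px
  x <- tan(m[, 1] * pi / 180) * geometry$distance_mm / sx + geometry$width_px / 2
  y <- tan(m[, 2] * pi / 180) * geometry$distance_mm / sy + geometry$height_px / 2
  out <- cbind(x, y)
  if (is.null(dim(deg))) out[1, ] else out
}

#' Regions of interest on and around the screen
#'
#' Axis-aligned rectangles for the partner's face (social RoI, a square sitting
#' above the lowered screen's top edge in gaze coordinates, hence negative y),
#' and the left/right stimulus bars in the upper half of the screen. Everything
#' not covered by these three rectangles is the "random" region.
#'
#' Rectangles are given as `c(xmin, ymin, xmax, ymax)` in pixels and must be
#' pairwise disjoint. Containment is inclusive on the min edges and exclusive
#' on the max edges, so shared boundaries are unambiguous.
#'
#' @param social,left_stim,right_stim Rectangles `c(xmin, ymin, xmax, ymax)`.
#' @return Object of class `roi_map`.
#' @export
roi_map <- function(social = c(810, -350, 1110, -50),
                    left_stim = c(160, 150, 560, 450),
                    right_stim = c(1360, 150, 1760, 450)) {
  rects <- list(social = social, left_stim = left_stim, right_stim = right_stim)
  for (nm in names(rects)) {
    r <- rects[[nm]]
    if (length(r) != 4 || any(!is.finite(r)) || r[3] <= r[1] || r[4] <= r[2])
      stop(sprintf("RoI '%s' must be c(xmin, ymin, xmax, ymax) with positive extent", nm),
           call. = FALSE)
  }
  overlap <- function(a, b)
    a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
  pairs <- utils::combn(names(rects), 2, simplify = FALSE)
  for (p in pairs)
    if (overlap(rects[[p[1]]], rects[[p[2]]]))
      stop(sprintf("RoIs '%s' and '%s' overlap", p[1], p[2]), call. = FALSE)
  structure(rects, class = "roi_map")
}

#' @export
print.roi_map <- function(x, ...) {
  cat("RoI map (px, [min, max) edges):\n")
  for (nm in names(unclass(x))) {
    r <- x[[nm]]
    cat(sprintf("  %-10s x [%g, %g), y [%g, %g)\n", nm, r[1], r[3], r[2], r[4]))
  }
  invisible(x)
}

#' Assign gaze positions to regions of interest
#'
#' Labels each point as `social`, `left_stim`, `right_stim`, or `random` by
#' rectangle containment, inclusive on min edges and exclusive on max edges.
#'
#' @param xy Length-2 vector or two-column matrix of pixel coordinates.
#' @param map A [roi_map()].
#' @return Character vector of labels.
#' @export
assign_roi <- function(xy, map = roi_map()) {
  stopifnot(inherits(map, "roi_map"))
  m <- if (is.null(dim(xy))) matrix(xy, ncol = 2) else as.matrix(xy)
  lab <- rep("random", nrow(m))
  for (nm in c("social", "left_stim", "right_stim")) {
    r <- map[[nm]]
    inside <- m[, 1] >= r[1] & m[, 1] < r[3] & m[, 2] >= r[2] & m[, 2] < r[4]
    lab[inside] <- nm
  }
  lab
}
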