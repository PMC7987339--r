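#' Spherocylindrical cell geometry
#'
#' Defines the 2D projection of a rod-shaped bacterium as a spherocylinder:
#' a rectangle of length \code{length - width} capped by two semicircles of
#' diameter \code{width}. The geometry also carries the membrane band width
#' (a boundary annulus) and the semi-axes of a centred elliptical nucleoid,
#' which together induce the nucleoid / membrane / cytoplasm partition used
#' for enrichment statistics.
#'
#' @param length total pole-to-pole cell length, in micrometres.
#' @param width cell width (diameter of the caps), in micrometres.
#' @param membrane_band width of the boundary annulus counted as membrane,
#'   in micrometres.
#' @param nucleoid_axes numeric pair: semi-axes (along the cell axis, across
#'   it) of the centred elliptical nucleoid, in micrometres. \code{c(0, 0)}
#'   means no nucleoid.
#' @return An object of class \code{cell_geometry}.
#' @examples
#' geom <- cell_geometry()
#' geom
#' @export
cell_geometry <- function(length = 3, width = 1, membrane_band = 0.173,
                          nucleoid_axes = c(1.0, 0.3)) {
  stopifnot(is.numeric(length), is.numeric(width), length > 0, width > 0)
  if (width > length)
    stop("cell width must not exceed cell length")
  if (membrane_band < 0 || membrane_band >= width / 2)
    stop("membrane_band must lie in [0, width/2)")
  nucleoid_axes <- as.numeric(nucleoid_axes)
  if (length(nucleoid_axes) != 2 || any(nucleoid_axes < 0))
    stop("nucleoid_axes must be a non-negative numeric pair")
  if (nucleoid_axes[1] > length / 2 || nucleoid_axes[2] > width / 2)
    stop("nucleoid ellipse must be contained in the cell interior")
  structure(
    list(length = length, width = width, membrane_band = membrane_band,
         nucleoid_axes = nucleoid_axes),
    class = "cell_geometry"
  )
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("Spherocylindrical cell geometry\n")
  cat(sprintf("  length x width : %.3g x %.3g um\n", x$length, x$width))
  cat(sprintf("  membrane band  : %.3g um\n", x$membrane_band))
  cat(sprintf("  nucleoid axes  : (%.3g, %.3g) um\n",
              x$nucleoid_axes[1], x$nucleoid_axes[2]))
  invisible(x)
}

# Signed distance bookkeeping for the spherocylinder: distance of (x, y)
# (cell-centred coordinates, axis along x) from the medial axis segment.
axis_distance <- function(x, y, geometry) {
  a <- (geometry$length - geometry$width) / 2
  dx <- pmax(abs(x) - a, 0)
  sqrt(dx^2 + y^2)
}

#' Test whether points lie inside the cell
#'
#' @param x,y coordinates in micrometres, in the cell-centred frame
#'   (origin at the cell centre, x along the long axis).
#' @param geometry a \code{\link{cell_geometry}}.
#' @return Logical vector.
#' @export
in_cell <- function(x, y, geometry) {
  axis_distance(x, y, geometry) <= geometry$width / 2
}

# Uniform sample of n points inside the spherocylinder (rejection sampling).
sample_in_cell <- function(n, geometry) {
  L <- geometry$length; W <- geometry$width
  out_x <- numeric(0); out_y <- numeric(0)
  while (length(out_x) < n) {
    m <- max(2 * (n - length(out_x)), 16)
    x <- stats::runif(m, -L / 2, L / 2)
    y <- stats::runif(m, -W / 2, W / 2)
    ok <- in_cell(x, y, geometry)
    out_x <- c(out_x, x[ok]); out_y <- c(out_y, y[ok])
  }
  cbind(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

# Reflect points that fell outside the spherocylinder back inside, across
# the nearest boundary point. Iterates for safety; steps are restricted to
# < width/4 upstream, so one pass almost always suffices.
reflect_into_cell <- function(x, y, geometry) {
  r <- geometry$width / 2
  a <- (geometry$length - geometry$width) / 2
  for (it in 1:20) {
    d <- axis_distance(x, y, geometry)
    out <- d > r
    if (!any(out)) break
    # nearest point on medial axis
    qx <- pmin(pmax(x[out], -a), a)
    dd <- d[out]
    scale <- (2 * r - dd) / dd
    x[out] <- qx + (x[out] - qx) * scale
    y[out] <- y[out] * scale
  }
  cbind(x = x, y = y)
}
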