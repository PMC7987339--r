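#' Construct region masks from a cell geometry
#'
#' Rasterizes the spherocylindrical cell onto a pixel grid (cell centred in
#' the image) and partitions it into membrane (boundary annulus of the
#' configured band width), nucleoid (centred ellipse, clipped to the cell
#' interior minus the membrane) and cytoplasm (the remainder). The three
#' regions are pairwise disjoint and tile the cell exactly, pixelwise.
#'
#' @param geometry a \code{\link{cell_geometry}}.
#' @param pixel_size um per pixel.
#' @param shape integer pair (rows, cols) of the mask grid.
#' @return An object of class \code{region_masks}: logical matrices
#'   \code{cell}, \code{nucleoid}, \code{membrane}, \code{cytoplasm} plus
#'   \code{pixel_size}.
#' @export
make_region_masks <- function(geometry, pixel_size, shape) {
  stopifnot(inherits(geometry, "cell_geometry"), pixel_size > 0,
            length(shape) == 2)
  ny <- shape[1]; nx <- shape[2]
  if (geometry$length > nx * pixel_size || geometry$width > ny * pixel_size)
    stop("geometry does not fit in the requested mask shape")
  band <- geometry$membrane_band
  if (band > 0 && band < pixel_size) {
    warning("membrane band thinner than one pixel; widened to one pixel")
    band <- pixel_size
  }
  cx <- nx * pixel_size / 2; cy <- ny * pixel_size / 2
  xs <- (seq_len(nx) - 0.5) * pixel_size - cx
  ys <- (seq_len(ny) - 0.5) * pixel_size - cy
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  d <- matrix(axis_distance(as.vector(X), as.vector(Y), geometry), ny, nx)
  r <- geometry$width / 2
  cell <- d <= r
  membrane <- cell & (d > r - band)
  ax <- geometry$nucleoid_axes
  nucleoid <- if (all(ax > 0))
    ((X / ax[1])^2 + (Y / ax[2])^2 <= 1) & cell & !membrane
  else matrix(FALSE, ny, nx)
  cytoplasm <- cell & !membrane & !nucleoid
  structure(list(cell = cell, nucleoid = nucleoid, membrane = membrane,
                 cytoplasm = cytoplasm, pixel_size = pixel_size),
            class = "region_masks")
}

#' @export
print.region_masks <- function(x, ...) {
  a <- vapply(x[c("cell", "membrane", "nucleoid", "cytoplasm")], sum, 1.0)
  cat("Region masks (px):",
      paste(sprintf("%s=%d", names(a), as.integer(a)), collapse = ", "),
      sprintf("| pixel %.3g um\n", x$pixel_size))
  invisible(x)
}

#' Derive region masks from a cell mask and a nucleoid stain image
#'
#' The membrane is the cell minus its binary erosion by a square
#' structuring element of half-width \code{band_px} (the boundary ring, as
#' read off a DIC outline); the nucleoid is the stain image thresholded by
#' Otsu's method within the cell and clipped to the cell interior minus the
#' membrane; the cytoplasm is the remainder, so the three regions partition
#' the cell.
#'
#' @param cell_mask logical matrix.
#' @param nucleoid logical mask, or a numeric stain image to be
#'   Otsu-thresholded within the cell.
#' @param band_px membrane band half-width in pixels (default 1).
#' @param pixel_size um per pixel (carried through, default 0.173).
#' @return A \code{region_masks} object.
#' @export
derive_regions <- function(cell_mask, nucleoid = NULL, band_px = 1,
                           pixel_size = 0.173) {
  stopifnot(is.matrix(cell_mask))
  cell <- cell_mask > 0
  kern <- EBImage::makeBrush(2 * band_px + 1, shape = "box")
  eroded <- EBImage::erode(EBImage::Image(cell * 1), kern) > 0.5
  eroded <- matrix(as.logical(eroded), nrow(cell), ncol(cell))
  membrane <- cell & !eroded
  if (is.null(nucleoid)) {
    nuc <- matrix(FALSE, nrow(cell), ncol(cell))
  } else if (is.logical(nucleoid) || all(nucleoid %in% c(0, 1))) {
    nuc <- (nucleoid > 0) & cell & !membrane
  } else {
    img <- nucleoid
    rng <- range(img[cell])
    if (diff(rng) == 0) {
      nuc <- matrix(FALSE, nrow(cell), ncol(cell))
    } else {
      sc <- (img - rng[1]) / diff(rng)
      sc[!cell] <- 0
      thr <- EBImage::otsu(EBImage::Image(sc), range = c(0, 1))
      nuc <- (sc > thr) & cell & !membrane
    }
  }
  if (!is.null(nucleoid) && !any(nuc & cell))
    if (!any(nuc)) warning("nucleoid stain has no overlap with the cell; empty nucleoid region")
  cytoplasm <- cell & !membrane & !nuc
  structure(list(cell = cell, nucleoid = nuc, membrane = membrane,
                 cytoplasm = cytoplasm, pixel_size = pixel_size),
            class = "region_masks")
}

# Map um positions to mask pixel indices (pixel (r, c) spans
# [(c-1) px, c px] x [(r-1) px, r px]).
position_to_pixel <- function(x_um, y_um, masks) {
  px <- masks$pixel_size
  r <- pmin(pmax(ceiling(y_um / px), 1L), nrow(masks$cell))
  c <- pmin(pmax(ceiling(x_um / px), 1L), ncol(masks$cell))
  cbind(row = r, col = c)
}

#' Subcellular enrichment of localizations
#'
#' Enrichment of a region is the fraction of in-cell localizations that
#' fall in the region divided by the region's share of the cell area; 1
#' means occupancy proportional to area. Localizations outside the cell
#' mask are dropped (their count is reported). When a step table is
#' supplied, the mean one-step speed per region (steps assigned by their
#' midpoint) is reported alongside.
#'
#' @param locs localization table (needs \code{x_um}, \code{y_um}).
#' @param masks a \code{region_masks} object.
#' @param steps optional \code{step_table} with a \code{speed_um_s} column
#'   (see \code{\link{compute_osd_speed}}).
#' @return An object of class \code{enrichment_result}: data.frame
#'   (\code{region}, \code{count}, \code{area_um2}, \code{enrichment},
#'   \code{mean_speed_um_s}) with attributes \code{n_total} (in-cell) and
#'   \code{n_dropped}.
#' @export
compute_enrichment <- function(locs, masks, steps = NULL) {
  stopifnot(inherits(masks, "region_masks"))
  regions <- c("nucleoid", "membrane", "cytoplasm")
  pix <- position_to_pixel(locs$x_um, locs$y_um, masks)
  lin <- cbind(pix[, "row"], pix[, "col"])
  in_cell <- masks$cell[lin]
  n_dropped <- sum(!in_cell)
  lin <- lin[in_cell, , drop = FALSE]
  n_total <- nrow(lin)
  px2 <- masks$pixel_size^2
  cell_px <- sum(masks$cell)
  res <- data.frame(region = regions, count = NA_integer_,
                    area_um2 = NA_real_, enrichment = NA_real_,
                    mean_speed_um_s = NA_real_)
  for (i in seq_along(regions)) {
    m <- masks[[regions[i]]]
    a_px <- sum(m)
    res$count[i] <- if (n_total > 0) sum(m[lin]) else 0L
    res$area_um2[i] <- a_px * px2
    res$enrichment[i] <- if (a_px == 0 || n_total == 0) NA_real_
      else (res$count[i] / n_total) / (a_px / cell_px)
  }
  if (!is.null(steps) && nrow(steps) > 0) {
    if (!"speed_um_s" %in% names(steps)) steps <- compute_osd_speed(steps)
    spix <- position_to_pixel(steps$x_mid, steps$y_mid, masks)
    slin <- cbind(spix[, "row"], spix[, "col"])
    keep <- masks$cell[slin]
    slin <- slin[keep, , drop = FALSE]
    sp <- steps$speed_um_s[keep]
    for (i in seq_along(regions)) {
      inside <- masks[[regions[i]]][slin]
      if (any(inside)) res$mean_speed_um_s[i] <- mean(sp[inside])
    }
  }
  structure(res, n_total = n_total, n_dropped = n_dropped,
            class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment over %d in-cell localizations (%d dropped outside)\n",
              attr(x, "n_total"), attr(x, "n_dropped")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
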