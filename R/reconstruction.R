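#' Detect candidate emitters in a single frame
#'
#' A pixel is a candidate when (a) its intensity is strictly above the
#' frame threshold — mean plus \code{k_sd} standard deviations of that
#' frame's pixel intensities (a pure multiple of the s.d. is meaningless for
#' cameras with a non-zero offset, so the frame mean is the baseline;
#' configurable) — and (b) it is maximal within its centred 5 x 5
#' neighbourhood, ties broken by keeping the lexicographically smallest
#' (row, col) pixel so one plateaued spot yields one candidate. Candidates
#' closer than 3 px to the border are dropped so the 7 x 7 fitting window
#' fits.
#'
#' @param frame numeric matrix (rows x cols).
#' @param k_sd threshold multiplier on the frame s.d. (default 3).
#' @param baseline \code{"mean"} (default) or \code{"zero"}: the offset
#'   added to \code{k_sd * sd}.
#' @return data.frame with columns \code{row}, \code{col} (integer pixel
#'   indices); zero rows when the frame is constant.
#' @export
detect_candidates <- function(frame, k_sd = 3, baseline = c("mean", "zero")) {
  stopifnot(is.matrix(frame), nrow(frame) >= 7, ncol(frame) >= 7)
  baseline <- match.arg(baseline)
  s <- stats::sd(frame)
  empty <- data.frame(row = integer(0), col = integer(0))
  if (!is.finite(s) || s == 0) return(empty)
  thr <- k_sd * s + if (baseline == "mean") mean(frame) else 0
  idx <- which(frame > thr, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  ny <- nrow(frame); nx <- ncol(frame)
  keep <- idx[, 1] >= 4 & idx[, 1] <= ny - 3 & idx[, 2] >= 4 & idx[, 2] <= nx - 3
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0) return(empty)
  ok <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    nb <- frame[(r - 2):(r + 2), (c - 2):(c + 2)]
    v <- frame[r, c]
    if (v < max(nb)) next
    # ties: survive only as the lexicographically smallest pixel at the max
    tie <- which(nb == v, arr.ind = TRUE)
    tr <- tie[, 1] + r - 3L; tc <- tie[, 2] + c - 3L
    first <- order(tr, tc)[1]
    ok[i] <- (tr[first] == r && tc[first] == c)
  }
  idx <- idx[ok, , drop = FALSE]
  ord <- order(idx[, 1], idx[, 2])
  data.frame(row = as.integer(idx[ord, 1]), col = as.integer(idx[ord, 2]))
}

# Pixel-integrated symmetric 2D Gaussian + constant offset on a window whose
# pixel centres are at integer (row, col). theta = (N, x0, y0, sigma, b).
gauss2d_model <- function(theta, rows, cols) {
  N <- theta[1]; x0 <- theta[2]; y0 <- theta[3]
  s <- theta[4]; b <- theta[5]
  fx <- stats::pnorm((cols + 0.5 - x0) / s) - stats::pnorm((cols - 0.5 - x0) / s)
  fy <- stats::pnorm((rows + 0.5 - y0) / s) - stats::pnorm((rows - 0.5 - y0) / s)
  N * outer(fy, fx) + b
}

#' Fit a 2D Gaussian to a 7 x 7 window around a candidate pixel
#'
#' Nonlinear least squares (Levenberg-Marquardt) of a symmetric
#' pixel-integrated 2D Gaussian plus constant offset. The fit is flagged as
#' failed (\code{fit_ok = FALSE}; such records are discarded downstream)
#' when the optimizer does not converge, the amplitude is non-positive, the
#' fitted sigma leaves [0.5, 3.5] px, or the centre leaves the window.
#'
#' @param frame numeric matrix.
#' @param row,col candidate pixel (at least 3 px from the border).
#' @param min_peak_snr fitted peak height must exceed this multiple of the
#'   fitted background's shot noise (default 3) for the fit to count as
#'   converged on a real spot.
#' @return One-row data.frame: \code{row}, \code{col}, \code{x_px},
#'   \code{y_px} (fitted centre; pixel c's centre is x_px = c),
#'   \code{photons}, \code{sigma_px}, \code{background}, \code{fit_ok},
#'   \code{rss}.
#' @export
fit_gaussian2d <- function(frame, row, col, min_peak_snr = 3) {
  ny <- nrow(frame); nx <- ncol(frame)
  stopifnot(row >= 4, row <= ny - 3, col >= 4, col <= nx - 3)
  rows <- (row - 3L):(row + 3L)
  cols <- (col - 3L):(col + 3L)
  win <- frame[rows, cols]
  b0 <- min(win)
  N0 <- max(sum(win - b0), 1e-6)
  w <- pmax(win - b0, 0)
  sw <- sum(w)
  if (sw > 0) {
    y0 <- sum(rows * rowSums(w)) / sw
    x0 <- sum(cols * colSums(w)) / sw
  } else { y0 <- row; x0 <- col }
  theta0 <- c(N = N0, x0 = x0, y0 = y0, sigma = 1.2, b = b0)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = theta0,
      fn = function(th) as.vector(gauss2d_model(th, rows, cols) - win),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  bad <- function(res) data.frame(
    row = row, col = col, x_px = NA_real_, y_px = NA_real_,
    photons = NA_real_, sigma_px = NA_real_, background = NA_real_,
    fit_ok = FALSE, rss = if (is.null(res)) NA_real_ else res)
  if (is.null(fit) || fit$info %in% c(0, 5)) return(bad(NULL))
  th <- fit$par
  # peak height must stand clear of the shot noise of the fitted
  # background, otherwise the "spot" is a noise fluctuation and the fit
  # counts as failed
  peak <- th[1] / (2 * pi * th[4]^2)
  significant <- peak > min_peak_snr * sqrt(max(th[5], 0))
  ok <- th[1] > 0 && significant && th[4] >= 0.5 && th[4] <= 3.5 &&
    th[2] >= min(cols) && th[2] <= max(cols) &&
    th[3] >= min(rows) && th[3] <= max(rows)
  data.frame(row = row, col = col, x_px = unname(th[2]), y_px = unname(th[3]),
             photons = unname(th[1]), sigma_px = unname(th[4]),
             background = unname(th[5]), fit_ok = ok,
             rss = sum(fit$fvec^2))
}

# Render localizations of a frame block into a 2D count histogram at
# `upsample` x resolution.
render_block <- function(x_px, y_px, ny, nx, upsample) {
  H <- matrix(0, ny * upsample, nx * upsample)
  r <- pmin(pmax(ceiling(y_px * upsample), 1L), ny * upsample)
  c <- pmin(pmax(ceiling(x_px * upsample), 1L), nx * upsample)
  for (i in seq_along(r)) H[r[i], c[i]] <- H[r[i], c[i]] + 1
  H
}

# Cross-correlation peak of B against A via FFT, with Gaussian
# regularization of both images and 3-point parabolic subpixel refinement.
# Returns the shift (dx, dy) such that B ~ A translated by (dx, dy).
xcorr_shift <- function(A, B, blur_sigma = 2) {
  d <- dim(A)
  # wrapped Gaussian kernel, applied to both images in Fourier space
  gy <- stats::dnorm(pmin(0:(d[1] - 1), d[1] - 0:(d[1] - 1)), 0, blur_sigma)
  gx <- stats::dnorm(pmin(0:(d[2] - 1), d[2] - 0:(d[2] - 1)), 0, blur_sigma)
  G <- stats::fft(outer(gy, gx))
  CC <- Re(stats::fft(stats::fft(B) * Conj(stats::fft(A)) * Mod(G)^2,
                      inverse = TRUE))
  pk <- which(CC == max(CC), arr.ind = TRUE)[1, ]
  refine <- function(m, i, n) {
    im <- if (i == 1) n else i - 1
    ip <- if (i == n) 1 else i + 1
    den <- m[im] - 2 * m[i] + m[ip]
    if (den == 0) 0 else 0.5 * (m[im] - m[ip]) / den
  }
  dy <- pk[1] - 1 + refine(CC[, pk[2]], pk[1], d[1])
  dx <- pk[2] - 1 + refine(CC[pk[1], ], pk[2], d[2])
  if (dy > d[1] / 2) dy <- dy - d[1]
  if (dx > d[2] / 2) dx <- dx - d[2]
  c(dx = unname(dx), dy = unname(dy))
}

#' Estimate lateral drift by Fourier cross-correlation of temporal blocks
#'
#' Localizations are grouped into blocks of \code{block_size} frames, each
#' block is rendered at \code{upsample}-fold resolution, and the
#' cross-correlation peak (computed via FFT, with subpixel parabolic
#' interpolation) of every block against the first gives the per-block
#' shift. A monotone frame-to-shift map is obtained by linear interpolation
#' between block centres.
#'
#' @param locs localization table with columns \code{frame}, \code{x_px},
#'   \code{y_px}.
#' @param block_size frames per block (default 1000).
#' @param img_size_px integer pair (rows, cols) of the source image.
#' @param upsample rendering upsampling factor for the correlation
#'   (default 2).
#' @return An object of class \code{drift_trace}: data.frame (\code{block},
#'   \code{frame_mid}, \code{dx_px}, \code{dy_px}) with the first block at
#'   (0, 0), plus an interpolator used by \code{\link{apply_drift}}.
#' @export
estimate_drift_fft <- function(locs, block_size = 1000, img_size_px,
                               upsample = 2) {
  stopifnot(all(c("frame", "x_px", "y_px") %in% names(locs)))
  f_max <- max(locs$frame)
  n_blocks <- ceiling(f_max / block_size)
  if (n_blocks < 2)
    stop("need at least 2 blocks with localizations to estimate drift")
  ny <- img_size_px[1]; nx <- img_size_px[2]
  block_of <- pmin((locs$frame - 1) %/% block_size + 1, n_blocks)
  ref <- NULL
  out <- data.frame(block = seq_len(n_blocks),
                    frame_mid = (seq_len(n_blocks) - 0.5) * block_size,
                    dx_px = 0, dy_px = 0)
  prev <- c(dx = 0, dy = 0)
  for (b in seq_len(n_blocks)) {
    sel <- block_of == b
    if (!any(sel)) {
      warning(sprintf("block %d has no localizations; carrying previous shift", b))
      out$dx_px[b] <- prev["dx"]; out$dy_px[b] <- prev["dy"]
      next
    }
    H <- render_block(locs$x_px[sel], locs$y_px[sel], ny, nx, upsample)
    if (is.null(ref)) { ref <- H; prev <- c(dx = 0, dy = 0) }
    else {
      sh <- xcorr_shift(ref, H, blur_sigma = upsample)
      prev <- sh / upsample
    }
    out$dx_px[b] <- prev["dx"]; out$dy_px[b] <- prev["dy"]
  }
  structure(list(blocks = out, block_size = block_size), class = "drift_trace")
}

#' @export
print.drift_trace <- function(x, ...) {
  cat(sprintf("Drift trace: %d blocks of %d frames; total drift (%.2f, %.2f) px\n",
              nrow(x$blocks), x$block_size,
              x$blocks$dx_px[nrow(x$blocks)], x$blocks$dy_px[nrow(x$blocks)]))
  invisible(x)
}

#' Apply a drift trace to a localization table
#'
#' Subtracts the interpolated per-frame drift from raw pixel positions and
#' refreshes the micrometre coordinates.
#'
#' @param locs localization table (needs \code{frame}, \code{x_px},
#'   \code{y_px}).
#' @param drift a \code{\link{estimate_drift_fft}} result.
#' @param pixel_size pixel size, um.
#' @return The corrected table.
#' @export
apply_drift <- function(locs, drift, pixel_size) {
  b <- drift$blocks
  # linear interpolation between block centres, linear extrapolation at the
  # ends (constant extrapolation under-corrects steady drift in the first
  # and last half-blocks)
  interp_extrap <- function(xout, y) {
    out <- stats::approx(b$frame_mid, y, xout = xout, rule = 2)$y
    n <- nrow(b)
    if (n >= 2) {
      lo <- xout < b$frame_mid[1]
      s1 <- (y[2] - y[1]) / (b$frame_mid[2] - b$frame_mid[1])
      out[lo] <- y[1] + s1 * (xout[lo] - b$frame_mid[1])
      hi <- xout > b$frame_mid[n]
      s2 <- (y[n] - y[n - 1]) / (b$frame_mid[n] - b$frame_mid[n - 1])
      out[hi] <- y[n] + s2 * (xout[hi] - b$frame_mid[n])
    }
    out
  }
  dx <- interp_extrap(locs$frame, b$dx_px)
  dy <- interp_extrap(locs$frame, b$dy_px)
  locs$x_px <- locs$x_px - dx
  locs$y_px <- locs$y_px - dy
  locs$x_um <- (locs$x_px - 0.5) * pixel_size
  locs$y_um <- (locs$y_px - 0.5) * pixel_size
  locs
}

#' Localize an image stack
#'
#' Runs candidate detection and 2D Gaussian fitting on every imaging frame
#' (activation frames are skipped), discards failed fits, corrects lateral
#' drift by block-wise Fourier cross-correlation when enough blocks are
#' available, and renders a super-resolution image as the sum of unit
#' Gaussians at the localization positions on an upsampled grid.
#'
#' @param stack an \code{image_stack} (or numeric array with a separate
#'   \code{descriptor}).
#' @param descriptor timing descriptor; defaults to the stack's own.
#' @param k_sd detection threshold multiplier.
#' @param drift_block_size frames per drift block; \code{NULL} disables
#'   drift correction.
#' @param render logical; also compute the rendered image.
#' @param render_upsample upsampling factor of the rendered image.
#' @return An object of class \code{localization_table}: data.frame
#'   (\code{frame}, \code{x_um}, \code{y_um}, \code{x_px}, \code{y_px},
#'   \code{photons}, \code{sigma_um}, \code{background}, \code{fit_ok})
#'   with attributes \code{descriptor}, \code{drift}, \code{rendered}.
#' @export
localize_stack <- function(stack, descriptor = NULL, k_sd = 3,
                           drift_block_size = 1000, render = FALSE,
                           render_upsample = 4) {
  if (inherits(stack, "image_stack")) {
    if (is.null(descriptor)) descriptor <- stack$descriptor
    stack <- stack$data
  }
  if (is.null(descriptor)) stop("an acquisition descriptor is required")
  nfr <- dim(stack)[3]
  if (!is.null(descriptor$n_frames) && descriptor$n_frames != nfr)
    stop(sprintf("descriptor says %d frames but stack has %d",
                 descriptor$n_frames, nfr))
  px <- descriptor$pixel_size
  act <- descriptor$activation_frames
  imaging <- setdiff(seq_len(nfr), act)
  recs <- vector("list", length(imaging))
  for (i in seq_along(imaging)) {
    f <- imaging[i]
    frame <- stack[, , f]
    cand <- detect_candidates(frame, k_sd = k_sd)
    if (nrow(cand) == 0) next
    fits <- do.call(rbind, lapply(seq_len(nrow(cand)), function(j)
      fit_gaussian2d(frame, cand$row[j], cand$col[j])))
    fits <- fits[fits$fit_ok, , drop = FALSE]
    if (nrow(fits) == 0) next
    fits$frame <- f
    recs[[i]] <- fits
  }
  locs <- do.call(rbind, recs)
  if (is.null(locs))
    locs <- data.frame(row = integer(0), col = integer(0), x_px = numeric(0),
                       y_px = numeric(0), photons = numeric(0),
                       sigma_px = numeric(0), background = numeric(0),
                       fit_ok = logical(0), rss = numeric(0),
                       frame = integer(0))
  drift <- NULL
  if (!is.null(drift_block_size) && nrow(locs) > 0 &&
      max(locs$frame) > drift_block_size) {
    drift <- tryCatch(
      estimate_drift_fft(locs, block_size = drift_block_size,
                         img_size_px = dim(stack)[1:2]),
      error = function(e) NULL)
  }
  locs$x_um <- (locs$x_px - 0.5) * px
  locs$y_um <- (locs$y_px - 0.5) * px
  if (!is.null(drift)) locs <- apply_drift(locs, drift, px)
  locs$sigma_um <- locs$sigma_px * px
  out <- locs[order(locs$frame),
              c("frame", "x_um", "y_um", "x_px", "y_px", "photons",
                "sigma_um", "background", "fit_ok")]
  rownames(out) <- NULL
  rendered <- NULL
  if (render)
    rendered <- render_localizations(out, dim(stack)[1:2], render_upsample)
  structure(out, descriptor = descriptor, drift = drift, rendered = rendered,
            class = c("localization_table", "data.frame"))
}

# Super-resolution rendering: sum of unit Gaussians (s.d. half an upsampled
# pixel) at the localization positions.
render_localizations <- function(locs, img_size_px, upsample = 4) {
  ny <- img_size_px[1] * upsample; nx <- img_size_px[2] * upsample
  img <- matrix(0, ny, nx)
  if (nrow(locs) == 0) return(img)
  s <- 0.5
  for (i in seq_len(nrow(locs))) {
    xc <- locs$x_px[i] * upsample; yc <- locs$y_px[i] * upsample
    c0 <- max(1, floor(xc - 3)); c1 <- min(nx, ceiling(xc + 3))
    r0 <- max(1, floor(yc - 3)); r1 <- min(ny, ceiling(yc + 3))
    if (c0 > c1 || r0 > r1) next
    g <- outer(stats::dnorm(r0:r1, yc, s), stats::dnorm(c0:c1, xc, s))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + g / sum(g)
  }
  img
}

#' Write a localization table to CSV
#'
#' @param locs a \code{localization_table}.
#' @param path output CSV path.
#' @export
write_localizations_csv <- function(locs, path) {
  utils::write.csv(as.data.frame(locs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations_csv
#' @export
read_localizations_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(df, class = c("localization_table", "data.frame"))
}
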