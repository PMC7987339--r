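#' Simulation configuration for photoactivation tracking movies
#'
#' Bundles the parameters of the forward model: a static mixture of diffusive
#' states, the activation/imaging frame interleaving, photophysics, and the
#' camera. Defaults emulate sparse photoactivated-emitter tracking in live
#' bacteria: ~174 frames per second (5.76 ms interval, 2.4 ms exposure),
#' 173 nm pixels, and ten imaging frames after each activation frame.
#'
#' @param states data.frame with columns \code{fraction} (unitless, summing
#'   to 1) and \code{D} (conventional 2D diffusion coefficient, um^2/s), one
#'   row per diffusive state.
#' @param loc_sigma localization error s.d. per axis, um.
#' @param frame_interval time between consecutive frames, s.
#' @param exposure camera exposure per frame, s (recorded; sampling is
#'   instantaneous unless \code{motion_blur} is set).
#' @param n_frames total number of frames (activation + imaging).
#' @param activation_period number of imaging frames following each
#'   activation frame.
#' @param mean_activations_per_pulse Poisson mean of new emitters per
#'   activation frame.
#' @param bleach_mean_frames mean photobleaching lifetime, frames
#'   (geometric).
#' @param photons_per_frame expected detected photons per emitter per frame.
#' @param background_photons_per_pixel expected background photons per pixel
#'   per frame.
#' @param pixel_size camera pixel size in sample space, um.
#' @param psf_sigma Gaussian PSF standard deviation, um.
#' @param img_size_px integer pair (rows, cols) of the field of view; by
#'   default sized to hold the cell with a 4-pixel margin (set when the
#'   geometry is known).
#' @param motion_blur logical; average emitter position over \code{exposure}
#'   sub-steps when rendering (off by default: instantaneous sampling).
#' @param seed integer seed making all simulator output reproducible.
#' @return An object of class \code{sim_config}.
#' @examples
#' cfg <- sim_config(states = data.frame(fraction = c(0.6, 0.4),
#'                                       D = c(0.05, 2.0)), seed = 1)
#' @export
sim_config <- function(states = data.frame(fraction = 1, D = 0.5),
                       loc_sigma = 0.03,
                       frame_interval = 0.00576,
                       exposure = 0.0024,
                       n_frames = 1100,
                       activation_period = 10,
                       mean_activations_per_pulse = 2,
                       bleach_mean_frames = 8,
                       photons_per_frame = 500,
                       background_photons_per_pixel = 5,
                       pixel_size = 0.173,
                       psf_sigma = 0.13,
                       img_size_px = NULL,
                       motion_blur = FALSE,
                       seed = 1L) {
  states <- as.data.frame(states)
  stopifnot(all(c("fraction", "D") %in% names(states)))
  if (abs(sum(states$fraction) - 1) > 1e-12)
    stop("state fractions must sum to 1 (tolerance 1e-12)")
  if (any(states$fraction < 0) || any(states$D < 0))
    stop("state fractions and diffusion coefficients must be non-negative")
  pos <- c(frame_interval = frame_interval, n_frames = n_frames,
           activation_period = activation_period,
           bleach_mean_frames = bleach_mean_frames,
           pixel_size = pixel_size, psf_sigma = psf_sigma)
  if (any(pos <= 0))
    stop("all rates and sizes must be positive: ",
         paste(names(pos)[pos <= 0], collapse = ", "))
  if (loc_sigma < 0 || exposure < 0 || photons_per_frame < 0 ||
      background_photons_per_pixel < 0 || mean_activations_per_pulse < 0)
    stop("negative parameter not allowed")
  structure(
    list(states = states, loc_sigma = loc_sigma,
         frame_interval = frame_interval, exposure = exposure,
         n_frames = as.integer(n_frames),
         activation_period = as.integer(activation_period),
         mean_activations_per_pulse = mean_activations_per_pulse,
         bleach_mean_frames = bleach_mean_frames,
         photons_per_frame = photons_per_frame,
         background_photons_per_pixel = background_photons_per_pixel,
         pixel_size = pixel_size, psf_sigma = psf_sigma,
         img_size_px = if (is.null(img_size_px)) NULL else
           as.integer(img_size_px),
         motion_blur = isTRUE(motion_blur), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Frames at which a 405 nm activation pulse is fired: one activation frame
# followed by activation_period imaging frames, repeating from frame 1.
activation_frames <- function(config) {
  seq.int(1L, config$n_frames, by = config$activation_period + 1L)
}

default_img_size <- function(config, geometry) {
  if (!is.null(config$img_size_px)) return(config$img_size_px)
  margin <- 4L
  nx <- as.integer(ceiling(geometry$length / config$pixel_size)) + 2L * margin
  ny <- as.integer(ceiling(geometry$width / config$pixel_size)) + 2L * margin
  c(ny, nx)
}

#' Simulate ground-truth emitter trajectories in a bacterial cell
#'
#' Photoactivated emitters appear at activation frames (Poisson number per
#' pulse), carry a fixed diffusive state drawn from the configured mixture
#' (no interconversion), perform 2D Brownian motion with reflective
#' boundaries on the spherocylinder, and bleach after a geometric number of
#' frames. Per-frame displacements have variance \code{2 * D *
#' frame_interval} per axis before reflection.
#'
#' @param config a \code{\link{sim_config}}.
#' @param geometry a \code{\link{cell_geometry}}.
#' @param confine logical; \code{FALSE} disables the reflective boundary
#'   (free 2D Brownian motion), used to check closed-form displacement
#'   statistics.
#' @return An object of class \code{ground_truth}: a list with
#'   \code{positions} (data.frame: emitter, frame, x_um, y_um, in the image
#'   frame where the cell centre sits at the field-of-view centre),
#'   \code{emitters} (emitter, state, D, activation_frame, bleach_frame),
#'   plus the config, geometry and the cell-centre offset.
#' @export
simulate_trajectories <- function(config, geometry, confine = TRUE) {
  stopifnot(inherits(config, "sim_config"), inherits(geometry, "cell_geometry"))
  sig_step <- sqrt(2 * max(config$states$D) * config$frame_interval)
  if (confine && sig_step > geometry$width / 4)
    stop("temporal resolution too coarse for confinement")
  set.seed(config$seed)
  img <- default_img_size(config, geometry)
  center <- c(x = img[2] * config$pixel_size / 2,
              y = img[1] * config$pixel_size / 2)

  act <- activation_frames(config)
  n_new <- stats::rpois(length(act), config$mean_activations_per_pulse)
  n_em <- sum(n_new)
  if (n_em == 0) {
    return(structure(list(
      positions = data.frame(emitter = integer(0), frame = integer(0),
                             x_um = numeric(0), y_um = numeric(0)),
      emitters = data.frame(emitter = integer(0), state = integer(0),
                            D = numeric(0), activation_frame = integer(0),
                            bleach_frame = integer(0)),
      config = config, geometry = geometry, center = center),
      class = "ground_truth"))
  }
  act_frame <- rep.int(act, n_new)
  state <- sample.int(nrow(config$states), n_em, replace = TRUE,
                      prob = config$states$fraction)
  D <- config$states$D[state]
  life <- stats::rgeom(n_em, prob = 1 / config$bleach_mean_frames) + 1L
  bleach_frame <- pmin(act_frame + life, config$n_frames)

  start <- sample_in_cell(n_em, geometry)
  pos_list <- vector("list", n_em)
  for (i in seq_len(n_em)) {
    frames <- seq.int(act_frame[i], bleach_frame[i])
    nf <- length(frames)
    sd_i <- sqrt(2 * D[i] * config$frame_interval)
    x <- numeric(nf); y <- numeric(nf)
    x[1] <- start[i, 1]; y[1] <- start[i, 2]
    if (nf > 1) {
      dx <- stats::rnorm(nf - 1, 0, sd_i)
      dy <- stats::rnorm(nf - 1, 0, sd_i)
      if (confine) {
        for (j in 2:nf) {
          p <- reflect_into_cell(x[j - 1] + dx[j - 1], y[j - 1] + dy[j - 1],
                                 geometry)
          x[j] <- p[1]; y[j] <- p[2]
        }
      } else {
        x <- x[1] + c(0, cumsum(dx))
        y <- y[1] + c(0, cumsum(dy))
      }
    }
    pos_list[[i]] <- data.frame(emitter = i, frame = frames,
                                x_um = x + center["x"], y_um = y + center["y"])
  }
  positions <- do.call(rbind, pos_list)
  rownames(positions) <- NULL
  structure(list(
    positions = positions,
    emitters = data.frame(emitter = seq_len(n_em), state = state, D = D,
                          activation_frame = act_frame,
                          bleach_frame = bleach_frame),
    config = config, geometry = geometry, center = center),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d emitters, %d position records, %d frames\n",
              nrow(x$emitters), nrow(x$positions), x$config$n_frames))
  invisible(x)
}

#' Render a simulated movie from ground-truth trajectories
#'
#' Forward imaging model: each emitter visible in an imaging frame is
#' rendered as a pixel-integrated 2D Gaussian (s.d. \code{psf_sigma}) whose
#' expected total intensity is \code{photons_per_frame}; per-pixel counts are
#' Poisson, on top of a uniform Poisson background. Activation frames carry
#' background only (the imaging channel is blind during the 405 nm pulse) and
#' are flagged in the timing descriptor.
#'
#' @param truth a \code{\link{simulate_trajectories}} result.
#' @param config a \code{\link{sim_config}} (normally \code{truth$config}).
#' @return An object of class \code{image_stack}: list with \code{data}
#'   (numeric array rows x cols x frames of photon counts) and
#'   \code{descriptor} (pixel_size, frame_interval, exposure, n_frames,
#'   activation_frames).
#' @export
render_movie <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(config$seed + 1L)
  img <- default_img_size(config, truth$geometry)
  ny <- img[1]; nx <- img[2]
  px <- config$pixel_size
  act <- activation_frames(config)
  stack <- array(0, dim = c(ny, nx, config$n_frames))

  pos <- truth$positions
  if (nrow(pos) > 0 &&
      (any(pos$x_um < 0) || any(pos$x_um > nx * px) ||
       any(pos$y_um < 0) || any(pos$y_um > ny * px)))
    stop("truth positions outside the field of view")

  # crowding check on the densest frame
  if (nrow(pos) > 1) {
    per_frame <- table(pos$frame)
    f <- as.integer(names(which.max(per_frame)))
    p <- pos[pos$frame == f, ]
    if (nrow(p) > 1) {
      dmat <- as.matrix(stats::dist(p[, c("x_um", "y_um")]))
      diag(dmat) <- Inf
      if (mean(apply(dmat, 1, min)) < 4 * config$psf_sigma)
        warning("overlapping emitters; localization accuracy not guaranteed")
    }
  }

  halfw <- max(3L, ceiling(5 * config$psf_sigma / px))
  sig_px <- config$psf_sigma / px
  imaging <- setdiff(seq_len(config$n_frames), act)
  pos_im <- pos[pos$frame %in% imaging, , drop = FALSE]
  if (nrow(pos_im) > 0 && config$photons_per_frame > 0) {
    for (i in seq_len(nrow(pos_im))) {
      xc <- pos_im$x_um[i] / px + 0.5   # pixel c has centre x_px = c
      yc <- pos_im$y_um[i] / px + 0.5
      c0 <- max(1L, floor(xc) - halfw); c1 <- min(nx, floor(xc) + halfw)
      r0 <- max(1L, floor(yc) - halfw); r1 <- min(ny, floor(yc) + halfw)
      if (c0 > c1 || r0 > r1) next
      cols <- c0:c1; rows <- r0:r1
      fx <- stats::pnorm((cols + 0.5 - xc) / sig_px) -
            stats::pnorm((cols - 0.5 - xc) / sig_px)
      fy <- stats::pnorm((rows + 0.5 - yc) / sig_px) -
            stats::pnorm((rows - 0.5 - yc) / sig_px)
      lam <- config$photons_per_frame * outer(fy, fx)
      f <- pos_im$frame[i]
      stack[rows, cols, f] <- stack[rows, cols, f] +
        stats::rpois(length(lam), lam)
    }
  }
  if (config$background_photons_per_pixel > 0)
    stack <- stack + array(
      stats::rpois(length(stack), config$background_photons_per_pixel),
      dim = dim(stack))

  structure(list(
    data = stack,
    descriptor = list(pixel_size = px,
                      frame_interval = config$frame_interval,
                      exposure = config$exposure,
                      n_frames = config$n_frames,
                      activation_frames = act)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Image stack: %d x %d px, %d frames (%d activation), %.3g nm pixels\n",
              d[1], d[2], d[3], length(x$descriptor$activation_frames),
              x$descriptor$pixel_size * 1000))
  invisible(x)
}

#' Write / read an image stack as multi-page TIFF
#'
#' The timing descriptor travels as a JSON side-car file
#' (\code{<path>.json}).
#'
#' @param stack an \code{image_stack}.
#' @param path output TIFF path.
#' @return \code{write_stack_tiff}: the path, invisibly.
#'   \code{read_stack_tiff}: an \code{image_stack}.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  nfr <- dim(stack$data)[3]
  scale <- 65535
  frames <- lapply(seq_len(nfr), function(f) stack$data[, , f] / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  desc <- stack$descriptor
  desc$intensity_scale <- scale
  jsonlite::write_json(desc, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param descriptor_path JSON descriptor path; defaults to
#'   \code{<path>.json}.
#' @export
read_stack_tiff <- function(path, descriptor_path = paste0(path, ".json")) {
  frames <- tiff::readTIFF(path, all = TRUE)
  desc <- jsonlite::read_json(descriptor_path, simplifyVector = TRUE)
  scale <- if (!is.null(desc$intensity_scale)) desc$intensity_scale else 65535
  desc$intensity_scale <- NULL
  arr <- array(0, dim = c(dim(frames[[1]]), length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- round(frames[[f]] * scale)
  structure(list(data = arr, descriptor = desc), class = "image_stack")
}

#' Simulate a rifampicin-chase decay series
#'
#' Generates normalized band intensities under the piecewise
#' delayed-exponential model: \code{I(t) = I0} for \code{t <= alpha} and
#' \code{I0 * exp(-k (t - alpha))} after the delay, multiplied by lognormal
#' noise with the stated coefficient of variation (unit mean).
#'
#' @param I0 intensity at time zero.
#' @param alpha initial delay before exponential decay, minutes.
#' @param k exponential decay rate, 1/min.
#' @param timepoints non-negative ascending sampling times, minutes.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param condition,replicate optional labels carried in the output.
#' @return A data.frame of class \code{decay_series}: columns
#'   \code{t_min}, \code{intensity}, \code{condition}, \code{replicate}.
#' @export
simulate_decay_series <- function(I0 = 1, alpha = 0, k = 0.2, timepoints,
                                  noise_cv = 0, seed = 1L,
                                  condition = "condition", replicate = 1L) {
  if (missing(timepoints) || length(timepoints) == 0)
    stop("timepoints must be a non-empty vector")
  if (is.unsorted(timepoints, strictly = FALSE) || any(timepoints < 0))
    stop("timepoints must be non-negative and ascending")
  if (k < 0 || alpha < 0) stop("k and alpha must be non-negative")
  set.seed(seed)
  I <- ifelse(timepoints <= alpha, I0, I0 * exp(-k * (timepoints - alpha)))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    I <- I * stats::rlnorm(length(I), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  structure(data.frame(t_min = timepoints, intensity = I,
                       condition = condition, replicate = replicate),
            class = c("decay_series", "data.frame"))
}

#' Draw one-step squared displacements from a diffusive-state mixture
#'
#' Under 2D Brownian motion with apparent (one-step) diffusion coefficient
#' D', the one-step squared displacement is exponential with mean
#' \code{4 * D' * t}; a static mixture of states gives the corresponding
#' exponential mixture. This is the direct generator behind the
#' mixture-model recovery checks.
#'
#' @param n number of steps.
#' @param fractions state weights (sum to 1).
#' @param D_prime apparent diffusion coefficients D', um^2/s.
#' @param t time interval between frames, s.
#' @param seed integer seed.
#' @return Numeric vector of squared displacements, um^2.
#' @export
simulate_osd2 <- function(n, fractions, D_prime, t = 0.00576, seed = 1L) {
  stopifnot(length(fractions) == length(D_prime),
            abs(sum(fractions) - 1) < 1e-9, all(D_prime >= 0), t > 0)
  set.seed(seed)
  state <- sample.int(length(fractions), n, replace = TRUE, prob = fractions)
  stats::rexp(n, rate = 1 / (4 * D_prime[state] * t))
}
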