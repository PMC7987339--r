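#' Ensemble mean squared displacement
#'
#' MSD at lag m * dt0 is the mean of |r(t + m dt0) - r(t)|^2 over all
#' trajectories and all start points. Trajectories are expected to be
#' length-filtered first (conventionally > 5 steps).
#'
#' @param trajs a \code{trajectory_set}.
#' @param max_lag largest lag in frames.
#' @param frame_interval seconds per frame (defaults to the set's
#'   attribute).
#' @return An object of class \code{msd_curve}: data.frame (\code{lag},
#'   \code{dt_s}, \code{msd_um2}, \code{n_pairs}).
#' @export
compute_msd_ensemble <- function(trajs, max_lag = 10, frame_interval = NULL) {
  if (is.null(frame_interval)) frame_interval <- attr(trajs, "frame_interval")
  if (is.null(frame_interval)) frame_interval <- 0.00576
  df <- as.data.frame(trajs)
  df <- df[order(df$traj_id, df$frame), ]
  by_traj <- split(df[, c("x_um", "y_um")], df$traj_id)
  longest <- max(vapply(by_traj, nrow, 1L)) - 1L
  if (longest < 1) stop("no trajectory with at least one step")
  if (max_lag > longest) {
    warning(sprintf("no trajectory supports lag %d; truncating to %d",
                    max_lag, longest))
    max_lag <- longest
  }
  sums <- numeric(max_lag); counts <- integer(max_lag)
  for (tr in by_traj) {
    np <- nrow(tr)
    for (m in seq_len(min(max_lag, np - 1))) {
      d2 <- (tr$x_um[(1 + m):np] - tr$x_um[1:(np - m)])^2 +
            (tr$y_um[(1 + m):np] - tr$y_um[1:(np - m)])^2
      sums[m] <- sums[m] + sum(d2)
      counts[m] <- counts[m] + length(d2)
    }
  }
  structure(data.frame(lag = seq_len(max_lag),
                       dt_s = seq_len(max_lag) * frame_interval,
                       msd_um2 = ifelse(counts > 0, sums / counts, NA_real_),
                       n_pairs = counts),
            class = c("msd_curve", "data.frame"))
}

#' Fit the linear MSD model MSD = D x Dt
#'
#' Zero-intercept least squares of the MSD curve over its first
#' \code{n_lags} lags, following the convention in which the slope itself
#' is reported as the effective diffusion coefficient D. For 2D Brownian
#' motion MSD = 4 D_conv Dt, so the conventional coefficient is the slope
#' divided by four; both are returned and \code{D_slope = 4 * D_conv}
#' holds exactly.
#'
#' @param curve an \code{msd_curve}.
#' @param n_lags number of initial lags used (>= 2; default 4).
#' @return An object of class \code{msd_fit} with elements \code{D_slope}
#'   (um^2/s, the slope), \code{D_conv} (= D_slope / 4), \code{n_lags},
#'   \code{rss}, \code{clamped}, \code{curve}.
#' @export
fit_msd_linear <- function(curve, n_lags = 4) {
  stopifnot(inherits(curve, "msd_curve"), n_lags >= 2)
  n_lags <- min(n_lags, nrow(curve))
  cv <- curve[seq_len(n_lags), ]
  cv <- cv[is.finite(cv$msd_um2), ]
  slope <- sum(cv$msd_um2 * cv$dt_s) / sum(cv$dt_s^2)
  clamped <- FALSE
  if (slope < 0) { slope <- 0; clamped <- TRUE }
  structure(list(D_slope = slope, D_conv = slope / 4, n_lags = n_lags,
                 rss = sum((cv$msd_um2 - slope * cv$dt_s)^2),
                 clamped = clamped, curve = curve),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat("Linear MSD fit (MSD = D x Dt, zero intercept)\n")
  cat(sprintf("  D (slope)     : %.4g um^2/s%s\n", x$D_slope,
              if (x$clamped) "  [clamped at 0]" else ""))
  cat(sprintf("  D_conv (D/4)  : %.4g um^2/s\n", x$D_conv))
  cat(sprintf("  lags used     : %d, RSS %.3g\n", x$n_lags, x$rss))
  invisible(x)
}

#' @export
coef.msd_fit <- function(object, ...) {
  c(D_slope = object$D_slope, D_conv = object$D_conv)
}

#' @export
predict.msd_fit <- function(object, newdata = NULL, ...) {
  dt <- if (is.null(newdata)) object$curve$dt_s else newdata
  object$D_slope * dt
}

#' @export
plot.msd_fit <- function(x, ...) {
  plot(x$curve$dt_s, x$curve$msd_um2, xlab = "time lag (s)",
       ylab = "MSD (um^2)", ...)
  graphics::abline(a = 0, b = x$D_slope, lty = 2)
  invisible(x)
}

#' Attach one-step speeds to a step table
#'
#' Speed of a step is osd / dt0, attached at the step midpoint; the frame
#' interval must be uniform across steps.
#'
#' @param steps a \code{step_table}.
#' @return The step table with a \code{speed_um_s} column.
#' @export
compute_osd_speed <- function(steps) {
  stopifnot(nrow(steps) > 0)
  dt <- unique(steps$dt_s)
  if (length(dt) > 1 &&
      diff(range(steps$dt_s)) > 1e-12 * max(steps$dt_s))
    stop("mixed frame intervals; osd speed requires a uniform dt0")
  steps$speed_um_s <- steps$osd_um / steps$dt_s
  steps
}

# Mixture CDF: F(x) = 1 - sum_i P_i exp(-x / (4 D'_i t))
mixture_cdf <- function(x, P, D_prime, t) {
  out <- 1
  for (i in seq_along(P))
    out <- out - P[i] * exp(-x / (4 * D_prime[i] * t))
  out
}

# theta = (log D'_1..n, a_1..n-1) with softmax weights (a_n = 0 fixed).
theta_to_param <- function(theta, n) {
  D_prime <- exp(theta[seq_len(n)])
  if (n == 1) return(list(P = 1, D_prime = D_prime))
  a <- c(theta[(n + 1):(2 * n - 1)], 0)
  e <- exp(a - max(a))
  list(P = e / sum(e), D_prime = D_prime)
}

#' Fit an n-state diffusion mixture to the CDF of squared displacements
#'
#' For a static mixture of n diffusive states, the one-step squared
#' displacement follows \code{CDF(osd2) = 1 - sum_i P_i exp(-osd2 / (4 D'_i
#' t))} with \code{sum P_i = 1}. The model is fit to the empirical CDF
#' evaluated on a quantile-spaced grid (so the dense small-displacement
#' region is not over-weighted) by Levenberg-Marquardt nonlinear least
#' squares with multi-start initialization. States are reported in
#' descending order of D', so state 1 is the fast (RNA-free) state; the
#' one-step coefficients are also reported on the conventional scale
#' \code{D_i = 4 * D'_i}. An optional box constraint restricts D'_1, as
#' when the fast state of transcription-inhibited reference cells anchors
#' the fits of all other conditions.
#'
#' @param osd2 squared one-step displacements, um^2 (>= 500 values).
#' @param n number of states (1, 2 or 3).
#' @param t frame interval entering the CDF, s (default 5.76 ms).
#' @param D1_constraint optional length-2 interval (um^2/s, D' scale)
#'   bounding the fast state's D'.
#' @param n_grid number of quantile grid points (default 200).
#' @param n_starts number of multi-start initializations (default 5).
#' @return An object of class \code{cdf_mixture_fit}: \code{n}, \code{P},
#'   \code{D_prime}, \code{D} (= 4 D'), \code{t}, \code{rss},
#'   \code{converged}, \code{degenerate}, \code{constraint}, \code{grid}.
#' @export
fit_cdf_mixture <- function(osd2, n, t = 0.00576, D1_constraint = NULL,
                            n_grid = 200, n_starts = 5) {
  osd2 <- osd2[is.finite(osd2) & osd2 >= 0]
  if (length(osd2) < 500)
    stop("need at least 500 squared-displacement samples")
  stopifnot(n %in% 1:3, t > 0)
  probs <- seq_len(n_grid) / (n_grid + 1)
  x <- unname(stats::quantile(osd2, probs, type = 7))
  y <- probs

  resid_fn <- function(theta) {
    p <- theta_to_param(theta, n)
    mixture_cdf(x, p$P, p$D_prime, t) - y
  }
  # quantile-based starts: split samples into n groups by size
  qs <- stats::quantile(osd2, (seq_len(n) - 0.5) / n)
  base_D <- pmax(qs / (4 * t), 1e-8)
  lower <- rep(-Inf, 2 * n - 1)
  upper <- rep(Inf, 2 * n - 1)
  if (!is.null(D1_constraint)) {
    D1_constraint <- sort(as.numeric(D1_constraint))
    stopifnot(length(D1_constraint) == 2, all(D1_constraint > 0))
    # slot n holds the largest (fast) D' after sorting of start values;
    # capping the other slots at the upper bound keeps the sorted fast
    # state inside the interval whichever slot ends up largest
    lower[n] <- log(D1_constraint[1])
    upper[seq_len(n)] <- log(D1_constraint[2])
  }
  best <- NULL
  set_starts <- lapply(seq_len(n_starts), function(s) {
    mult <- if (s == 1) rep(1, n) else exp(stats::runif(n, -1.2, 1.2))
    d0 <- sort(base_D * mult)   # ascending; slot n = fastest
    if (!is.null(D1_constraint))
      d0[n] <- min(max(d0[n], D1_constraint[1]), D1_constraint[2])
    c(log(d0), rep(0, n - 1))
  })
  for (th0 in set_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info %in% c(0, 5)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("mixture fit did not converge from any start (n = ", n, ")")
  p <- theta_to_param(best$fit$par, n)
  ord <- order(p$D_prime, decreasing = TRUE)   # state 1 = fast
  D_prime <- p$D_prime[ord]; P <- p$P[ord]
  degenerate <- n > 1 &&
    any(abs(diff(D_prime)) / D_prime[-n] < 0.10)
  if (degenerate) warning("degenerate states: fitted D' values within 10%")
  structure(list(n = n, P = unname(P), D_prime = unname(D_prime),
                 D = unname(4 * D_prime), t = t, rss = best$rss,
                 converged = TRUE, degenerate = degenerate,
                 constraint = D1_constraint,
                 grid = data.frame(osd2 = x, ecdf = y),
                 n_samples = length(osd2)),
            class = "cdf_mixture_fit")
}

#' @export
print.cdf_mixture_fit <- function(x, ...) {
  cat(sprintf("%d-state squared-displacement mixture fit (t = %.4g ms, %d steps)\n",
              x$n, x$t * 1000, x$n_samples))
  for (i in seq_len(x$n))
    cat(sprintf("  state %d: P = %.3f, D' = %.4g um^2/s (D = 4D' = %.4g)\n",
                i, x$P[i], x$D_prime[i], x$D[i]))
  if (!is.null(x$constraint))
    cat(sprintf("  D'_1 constrained to [%.4g, %.4g]\n",
                x$constraint[1], x$constraint[2]))
  cat(sprintf("  RSS on %d-point CDF grid: %.4g\n", nrow(x$grid), x$rss))
  invisible(x)
}

#' @export
coef.cdf_mixture_fit <- function(object, ...) {
  stats::setNames(c(object$P, object$D_prime),
                  c(paste0("P", seq_len(object$n)),
                    paste0("Dprime", seq_len(object$n))))
}

#' @export
predict.cdf_mixture_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$grid$osd2 else newdata
  mixture_cdf(x, object$P, object$D_prime, object$t)
}

#' @export
plot.cdf_mixture_fit <- function(x, ...) {
  plot(x$grid$osd2, x$grid$ecdf, xlab = "osd^2 (um^2)", ylab = "CDF", ...)
  xs <- seq(0, max(x$grid$osd2), length.out = 300)
  graphics::lines(xs, predict(x, xs), lty = 2)
  invisible(x)
}

#' Choose the number of diffusive states
#'
#' Fits 1-, 2- and 3-state mixtures and selects the smallest n whose
#' successor improves the residual sum of squares by less than
#' \code{factor} (default 3x): additional states are only accepted while
#' they still buy a substantial improvement. A genuine extra state improves
#' the CDF residual by orders of magnitude, while overfitting noise on the
#' quantile grid buys at most a factor of about two, so the default
#' separates the two regimes.
#'
#' @inheritParams fit_cdf_mixture
#' @param factor required RSS improvement ratio to accept one more state.
#' @param n_max largest state count tried (default 3).
#' @return List: \code{chosen} (n), \code{fits} (per-n
#'   \code{cdf_mixture_fit}), \code{rss} (named vector).
#' @export
select_state_number <- function(osd2, t = 0.00576, factor = 3,
                                D1_constraint = NULL, n_max = 3, ...) {
  fits <- list()
  for (n in seq_len(n_max))
    # overfitted candidates routinely collapse onto near-identical states;
    # that is informative for selection, not a user-facing warning
    fits[[n]] <- withCallingHandlers(
      fit_cdf_mixture(osd2, n = n, t = t, D1_constraint = D1_constraint, ...),
      warning = function(w) {
        if (grepl("degenerate states", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  rss <- vapply(fits, function(f) f$rss, 1.0)
  chosen <- n_max
  for (n in seq_len(n_max - 1)) {
    if (rss[n] / rss[n + 1] < factor) { chosen <- n; break }
  }
  list(chosen = chosen, fits = fits,
       rss = stats::setNames(rss, paste0("n", seq_len(n_max))))
}

#' Reference interval constraining the fast state
#'
#' Replicate fits of a reference condition (transcription-inhibited cells,
#' where most of the tracked protein is RNA-free) define the admissible
#' range of the fast-state coefficient for all other conditions:
#' mean(D1) +/- 2 * sample-sd(D1) across replicates, returned on both the
#' conventional D scale and the D' = D/4 scale used for box-bounding.
#'
#' @param reference_fits list of \code{cdf_mixture_fit} objects
#'   (replicates).
#' @return List: \code{D1_interval} (conventional scale, = 4 D'),
#'   \code{D_prime_interval}, \code{mean}, \code{sd}, \code{n}.
#' @export
constrain_from_reference <- function(reference_fits) {
  stopifnot(length(reference_fits) >= 1,
            all(vapply(reference_fits, inherits, TRUE, "cdf_mixture_fit")))
  D1 <- vapply(reference_fits, function(f) f$D[1], 1.0)
  if (length(D1) == 1) {
    warning("single replicate: degenerate constraint interval [d, d]")
    iv <- c(D1, D1)
    s <- 0
  } else {
    s <- stats::sd(D1)
    iv <- mean(D1) + c(-2, 2) * s
  }
  iv <- pmax(iv, .Machine$double.eps)
  list(D1_interval = iv, D_prime_interval = iv / 4,
       mean = mean(D1), sd = s, n = length(D1))
}
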