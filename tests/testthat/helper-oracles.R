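# Independent brute-force oracles used to cross-check the implementation.

# Exhaustive candidate scan: applies the threshold and 5x5-maximality rules
# pixel by pixel, with the lexicographic tie-break, independently of
# detect_candidates().
oracle_candidates <- function(frame, k_sd = 3) {
  ny <- nrow(frame); nx <- ncol(frame)
  s <- stats::sd(frame)
  if (s == 0) return(data.frame(row = integer(0), col = integer(0)))
  thr <- mean(frame) + k_sd * s
  out <- NULL
  for (r in 4:(ny - 3)) for (c in 4:(nx - 3)) {
    v <- frame[r, c]
    if (v <= thr) next
    is_max <- TRUE
    smaller_tie <- FALSE
    for (dr in -2:2) for (dc in -2:2) {
      w <- frame[r + dr, c + dc]
      if (w > v) is_max <- FALSE
      if (w == v && (dr < 0 || (dr == 0 && dc < 0))) smaller_tie <- TRUE
    }
    if (is_max && !smaller_tie) out <- rbind(out, c(r, c))
  }
  if (is.null(out)) return(data.frame(row = integer(0), col = integer(0)))
  data.frame(row = out[, 1], col = out[, 2])
}

# Optimal one-to-one assignment between two point sets by exhaustive
# enumeration (minimum total distance; links above max_disp forbidden).
oracle_assign <- function(prev, cur, max_disp) {
  np <- nrow(prev); nc <- nrow(cur)
  k <- min(np, nc)
  best <- NULL; best_cost <- Inf
  # enumerate injective maps cur -> prev (including partial via NA padding)
  idx_sets <- utils::combn(np, min(k, np), simplify = FALSE)
  perm <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perm(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  for (kk in 0:k) {
    cur_sets <- if (kk == 0) list(integer(0)) else
      utils::combn(nc, kk, simplify = FALSE)
    prev_sets <- if (kk == 0) list(integer(0)) else
      utils::combn(np, kk, simplify = FALSE)
    for (cs in cur_sets) for (ps in prev_sets) {
      for (pp in perm(ps)) {
        d <- sqrt((prev[pp, 1] - cur[cs, 1])^2 + (prev[pp, 2] - cur[cs, 2])^2)
        if (length(d) && any(d > max_disp)) next
        cost <- sum(d) - 1e6 * kk   # prefer more links, then shorter
        if (cost < best_cost) { best_cost <- cost; best <- cbind(prev = pp, cur = cs) }
      }
    }
  }
  best
}

# Grid-search oracle for the piecewise decay model: profiles (alpha, k) on a
# fine grid with the closed-form intercept.
oracle_decay_grid <- function(t, I, alpha_max, alphas = seq(0, alpha_max, by = 0.02),
                              ks = seq(0, 1, by = 0.002)) {
  lnI <- log(I)
  best <- list(rss = Inf)
  for (a in alphas) {
    X <- pmax(t - a, 0)
    for (k in ks) {
      b <- mean(lnI + k * X)
      rss <- sum((b - k * X - lnI)^2)
      if (rss < best$rss) best <- list(rss = rss, alpha = a, k = k, b = b)
    }
  }
  best
}

# Small simulated movie shared by reconstruction tests.
make_static_movie <- function(seed = 3, n_frames = 330, activations = 0.35,
                              photons = 500) {
  geom <- cell_geometry()
  cfg <- sim_config(states = data.frame(fraction = 1, D = 0), loc_sigma = 0,
                    n_frames = n_frames,
                    mean_activations_per_pulse = activations,
                    bleach_mean_frames = 5, photons_per_frame = photons,
                    background_photons_per_pixel = 5, seed = seed)
  truth <- simulate_trajectories(cfg, geom)
  stack <- render_movie(truth, cfg)
  list(truth = truth, stack = stack, cfg = cfg, geom = geom)
}
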