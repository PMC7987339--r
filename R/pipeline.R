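#' Build a pipeline configuration
#'
#' Collects per-stage parameters with validated defaults; every source of
#' randomness derives from the single top-level seed. Unknown stage or
#' parameter names are rejected so typos cannot silently fall back to
#' defaults. The configuration round-trips unchanged through JSON
#' (\code{\link{write_pipeline_config}} / \code{\link{read_pipeline_config}}).
#'
#' @param seed top-level integer seed.
#' @param ... named stage overrides, each a named list; stages:
#'   \code{simulate} (sim_config arguments plus \code{geometry} list),
#'   \code{localize} (\code{k_sd}, \code{drift_block_size}),
#'   \code{track} (\code{max_disp}, \code{min_steps_msd},
#'   \code{min_steps_osd}), \code{diffuse} (\code{n_states}, \code{n_lags},
#'   \code{max_lag}, \code{select_n}), \code{enrich} (\code{enabled}),
#'   \code{decay} (\code{enabled}, \code{conditions}, \code{timepoints},
#'   \code{noise_cv}, \code{n_replicates}, \code{alpha_max}).
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  defaults <- list(
    simulate = list(
      geometry = list(length = 3, width = 1, membrane_band = 0.173,
                      nucleoid_axes = c(1.0, 0.3)),
      states = list(fraction = c(0.6, 0.4), D = c(0.05, 2.0)),
      loc_sigma = 0.03, frame_interval = 0.00576, exposure = 0.0024,
      n_frames = 1100, activation_period = 10,
      mean_activations_per_pulse = 2, bleach_mean_frames = 8,
      photons_per_frame = 500, background_photons_per_pixel = 5,
      pixel_size = 0.173, psf_sigma = 0.13),
    localize = list(k_sd = 3, drift_block_size = 1000),
    track = list(max_disp = 0.400, min_steps_msd = 5, min_steps_osd = 3),
    diffuse = list(n_states = 2, n_lags = 4, max_lag = 6, select_n = FALSE),
    enrich = list(enabled = TRUE),
    decay = list(enabled = FALSE,
                 conditions = list(wt = list(I0 = 1, alpha = 1, k = 0.35),
                                   mutant = list(I0 = 1, alpha = 1, k = 0.12)),
                 timepoints = c(0, 1, 2, 4, 6, 8, 12, 16),
                 noise_cv = 0.1, n_replicates = 4, alpha_max = 8)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown pipeline stage(s): ", paste(unknown, collapse = ", "))
  for (stage in names(overrides)) {
    ov <- overrides[[stage]]
    bad <- setdiff(names(ov), names(defaults[[stage]]))
    if (length(bad))
      stop("unknown parameter(s) in stage '", stage, "': ",
           paste(bad, collapse = ", "))
    defaults[[stage]][names(ov)] <- ov
  }
  defaults$seed <- as.integer(seed)
  structure(defaults, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  stages <- setdiff(names(raw), "seed")
  do.call(pipeline_config, c(list(seed = raw$seed), raw[stages]))
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes simulate -> render -> localize -> track -> diffusion analysis
#' (-> enrichment), and/or the decay branch, as configured, and assembles a
#' machine-readable report embedding the fully resolved configuration, the
#' seed and the package version. Reruns with the same configuration are
#' bit-identical.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir optional directory; when given, the report is written to
#'   \code{report.json} and stage tables to CSV files there.
#' @return The report, invisibly: a list with elements \code{config},
#'   \code{tracking} (localization / trajectory counts, MSD fit, mixture
#'   fit, enrichment) and/or \code{decay}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  report <- list(config = unclass(config),
                 package_version = as.character(utils::packageVersion("sptq")))

  sim <- config$simulate
  geom <- do.call(cell_geometry, sim$geometry)
  cfg <- sim_config(states = data.frame(fraction = sim$states$fraction,
                                        D = sim$states$D),
                    loc_sigma = sim$loc_sigma,
                    frame_interval = sim$frame_interval,
                    exposure = sim$exposure, n_frames = sim$n_frames,
                    activation_period = sim$activation_period,
                    mean_activations_per_pulse = sim$mean_activations_per_pulse,
                    bleach_mean_frames = sim$bleach_mean_frames,
                    photons_per_frame = sim$photons_per_frame,
                    background_photons_per_pixel = sim$background_photons_per_pixel,
                    pixel_size = sim$pixel_size, psf_sigma = sim$psf_sigma,
                    seed = config$seed)
  truth <- simulate_trajectories(cfg, geom)
  stack <- render_movie(truth, cfg)
  locs <- localize_stack(stack, k_sd = config$localize$k_sd,
                         drift_block_size = config$localize$drift_block_size)
  trajs <- link_localizations(locs, max_disp = config$track$max_disp)
  trajs_msd <- filter_trajectories(trajs, config$track$min_steps_msd)
  trajs_osd <- filter_trajectories(trajs, config$track$min_steps_osd)
  steps <- compute_osd_speed(trajectory_steps(trajs_osd))

  msd_fit <- NULL
  if (nrow(trajs_msd) > 0) {
    msd <- compute_msd_ensemble(trajs_msd, max_lag = config$diffuse$max_lag)
    msd_fit <- fit_msd_linear(msd, n_lags = config$diffuse$n_lags)
  }
  mix <- NULL; selection <- NULL
  if (nrow(steps) >= 500) {
    if (isTRUE(config$diffuse$select_n)) {
      selection <- select_state_number(steps$osd2_um2, t = cfg$frame_interval)
      mix <- selection$fits[[selection$chosen]]
    } else {
      mix <- fit_cdf_mixture(steps$osd2_um2, n = config$diffuse$n_states,
                             t = cfg$frame_interval)
    }
  }
  enrich <- NULL
  if (isTRUE(config$enrich$enabled)) {
    masks <- make_region_masks(geom, cfg$pixel_size,
                               default_img_size(cfg, geom))
    enrich <- compute_enrichment(locs, masks, steps = steps)
  }
  report$tracking <- list(
    n_localizations = nrow(locs),
    n_trajectories = length(unique(trajs$traj_id)),
    n_steps = nrow(steps),
    msd = if (!is.null(msd_fit))
      list(D_slope = msd_fit$D_slope, D_conv = msd_fit$D_conv),
    mixture = if (!is.null(mix))
      list(n = mix$n, P = mix$P, D_prime = mix$D_prime, D = mix$D,
           rss = mix$rss),
    state_selection = if (!is.null(selection))
      list(chosen = selection$chosen, rss = as.list(selection$rss)),
    enrichment = if (!is.null(enrich))
      as.list(stats::setNames(enrich$enrichment, enrich$region)))

  if (isTRUE(config$decay$enabled)) {
    dc <- config$decay
    fits <- list()
    ci <- 0
    for (cond in names(dc$conditions)) {
      ci <- ci + 1
      pars <- dc$conditions[[cond]]
      fits[[cond]] <- lapply(seq_len(dc$n_replicates), function(r) {
        s <- simulate_decay_series(I0 = pars$I0, alpha = pars$alpha,
                                   k = pars$k, timepoints = dc$timepoints,
                                   noise_cv = dc$noise_cv,
                                   seed = config$seed + 1000L * ci + r,
                                   condition = cond, replicate = r)
        fit_piecewise_decay(s, alpha_max = dc$alpha_max)
      })
    }
    cmp <- compare_half_lives(fits)
    report$decay <- list(summary = cmp$summary, pairwise = cmp$pairwise)
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    write_localizations_csv(locs, file.path(out_dir, "localizations.csv"))
    utils::write.csv(as.data.frame(trajs), file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(steps), file.path(out_dir, "steps.csv"),
                     row.names = FALSE)
  }
  invisible(report)
}
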