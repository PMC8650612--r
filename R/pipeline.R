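# Pipeline drivers: streaming profiles from a simulation, the image-based
# tracking pipeline, and a multi-seed orchestrator that chains
# simulate -> density -> corona -> tracks -> report on disk.

#' Radial-profile series from a simulation (streaming)
#'
#' Renders each requested frame, binarizes it and reduces it to a radial
#' profile immediately, so full image stacks are never held in memory. The
#' colony centre is estimated once from the first frame and reused for all
#' later times. Rendering is seeded from `params$seed`, so the series is
#' reproducible and identical to what [render_frames()] would produce for
#' the same times.
#'
#' @param sim a `colony_sim`.
#' @param times frame times (default: all recorded snapshots).
#' @param block_size,offset see [binarize_adaptive()].
#' @param bin_width profile bin width (um).
#' @param center colony centre, or `NULL` to estimate from the first frame.
#' @return list of [radial_profile()]s; attribute `center`.
#' @export
profile_series <- function(sim, times = sim$frame_times, block_size = 51,
                           offset = -20, bin_width = 30, center = NULL) {
  set.seed(sim$params$seed + 1000003L)
  ps <- sim$params$pixel_size
  profiles <- vector("list", length(times))
  for (k in seq_along(times)) {
    fr <- render_frame(agents_at(sim, times[k]), sim$params)
    bf <- binarize_adaptive(fr, block_size, offset, pixel_size = ps,
                            time = times[k])
    if (k == 1 && is.null(center)) center <- estimate_center(bf)
    profiles[[k]] <- radial_profile(bf, center, bin_width)
  }
  attr(profiles, "center") <- center
  profiles
}

#' Image-based tracking pipeline
#'
#' Renders frames over a tracking window, detects cells, links them into
#' tracks and computes per-interval velocity samples, mirroring the
#' single-cell tracking protocol (30-min window at 3 frames/min, typical
#' size 10 um, maximum speed 10 um/min, 1-min velocity intervals).
#'
#' @param sim a `colony_sim` whose recorded snapshots cover the window.
#' @param t_start window start (min).
#' @param duration_min window length (min).
#' @param fps frames per minute.
#' @param feature_diameter,max_speed tracking parameters (um, um/min).
#' @param interval velocity sampling interval (min).
#' @param speed_floor ratio speed floor (um/min).
#' @param center colony centre, or `NULL` to estimate from the first frame
#'   of the window.
#' @return list: `tracks`, `samples`, `center`, `times`.
#' @export
track_pipeline <- function(sim, t_start = 0, duration_min = 30, fps = 3,
                           feature_diameter = 10, max_speed = 10,
                           interval = 1, speed_floor = 0.5, center = NULL) {
  times <- t_start + seq(0, duration_min, by = 1 / fps)
  set.seed(sim$params$seed + 2000003L)
  ps <- sim$params$pixel_size
  detections <- vector("list", length(times))
  for (k in seq_along(times)) {
    fr <- render_frame(agents_at(sim, times[k]), sim$params)
    if (k == 1 && is.null(center)) {
      bf <- binarize_adaptive(fr, pixel_size = ps, time = times[k])
      center <- estimate_center(bf)
    }
    detections[[k]] <- detect_spots(fr, ps, feature_diameter, time = times[k])
  }
  tracks <- link_tracks(detections, times, max_speed)
  samples <- velocity_samples(tracks, center, interval, speed_floor)
  list(tracks = tracks, samples = samples, center = center, times = times)
}

#' Run configuration
#'
#' A fully serialisable description of a multi-seed pipeline run; the
#' resolved configuration is written beside the outputs so any run directory
#' can be reproduced from it.
#'
#' @param preset a [colony_preset()] name.
#' @param overrides named list of [colony_params()] overrides.
#' @param seeds integer vector of seeds (one run per seed).
#' @param out_dir output directory.
#' @param stages stages to execute, in order.
#' @param frame_cadence density-frame cadence (min).
#' @param tracking list: `t_start` (`"mid"` or minutes), `duration_min`,
#'   `fps`, `n_min`.
#' @param write_images write TIFF stacks of the density frames.
#' @param skip_existing skip stages whose outputs already exist.
#' @return a `run_config` list.
#' @export
run_config <- function(preset = "AX2-confined", overrides = list(),
                       seeds = 1L, out_dir = tempfile("coronakit_run"),
                       stages = c("simulate", "density", "corona", "report"),
                       frame_cadence = 5, tracking = list(),
                       write_images = FALSE, skip_existing = FALSE) {
  structure(list(preset = preset, overrides = overrides,
                 seeds = as.integer(seeds), out_dir = out_dir,
                 stages = stages, frame_cadence = frame_cadence,
                 tracking = utils::modifyList(
                   list(t_start = "mid", duration_min = 30, fps = 3, n_min = 200),
                   tracking),
                 write_images = write_images, skip_existing = skip_existing),
            class = "run_config")
}

#' Execute a pipeline run
#'
#' Runs the requested stages for every seed: `simulate` writes the agent
#' table and ground-truth ring trace (optionally a TIFF stack), `density`
#' writes the radial-profile series, `corona` writes the corona trace and a
#' kinetics summary, `tracks` writes velocity samples, the sliding-window
#' directionality profile and a fixed-mean von Mises fit, `report`
#' aggregates per-seed kinetics into mean +/- sd. A failed stage halts its
#' dependents for that seed; other seeds continue. With `skip_existing`,
#' stages whose output files are present are not recomputed.
#'
#' @param config a [run_config()].
#' @return a `report_summary` list (also written as `summary.json`):
#'   per-run kinetics and, when aggregation is possible, mean +/- sd of
#'   T*, v_i and v_f over successful runs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  runs <- lapply(config$seeds, function(seed) {
    run_one_seed(config, seed)
  })
  names(runs) <- paste0("seed", config$seeds)
  summary <- list(runs = lapply(runs, function(r) r[setdiff(names(r), "error")]),
                  errors = Filter(Negate(is.null),
                                  lapply(runs, function(r) r$error)))
  if ("report" %in% config$stages) {
    agg <- function(field) {
      v <- unlist(lapply(runs, function(r) r$kinetics[[field]]))
      v <- v[is.finite(v)]
      if (length(v) == 0) return(NULL)
      list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
           n = length(v))
    }
    summary$aggregate <- Filter(Negate(is.null),
                                list(T_star = agg("T_star"), v_i = agg("v_i"),
                                     v_f = agg("v_f")))
  }
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  class(summary) <- "report_summary"
  summary
}

run_one_seed <- function(config, seed) {
  rd <- file.path(config$out_dir, paste0("run_seed", seed))
  dir.create(rd, recursive = TRUE, showWarnings = FALSE)
  out <- list(seed = seed, dir = rd, kinetics = NULL, ring_absent = NA,
              error = NULL)
  params <- do.call(colony_preset,
                    c(list(name = config$preset, seed = seed),
                      config$overrides))
  t_end <- params$duration * 60
  frame_times <- seq(0, t_end, by = config$frame_cadence)

  sim <- NULL
  need <- function(stage) stage %in% config$stages
  exists_all <- function(...) all(file.exists(file.path(rd, c(...))))

  get_sim <- function() {
    if (is.null(sim)) sim <<- simulate_colony(params, frame_times)
    sim
  }

  try_stage <- function(name, outputs, fun) {
    if (!need(name)) return(TRUE)
    if (config$skip_existing && exists_all(outputs)) return(TRUE)
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     out$error <<- paste0(name, ": ", conditionMessage(e))
                     FALSE
                   })
    ok
  }

  ok <- try_stage("simulate", c("agents.csv", "ring.csv"), function() {
    s <- get_sim()
    write_agents_csv(s$agents, file.path(rd, "agents.csv"))
    utils::write.csv(s$ring, file.path(rd, "ring.csv"), row.names = FALSE)
    if (config$write_images)
      write_stack(render_frames(s), file.path(rd, "stack.tif"))
  })

  ok <- ok && try_stage("density", "profiles.csv", function() {
    profs <- profile_series(get_sim())
    write_profiles_csv(profs, file.path(rd, "profiles.csv"))
  })

  ok <- ok && try_stage("corona", c("trace.csv", "kinetics.json"), function() {
    profs <- read_profiles_csv(file.path(rd, "profiles.csv"))
    trace <- corona_trace(profs)
    utils::write.csv(trace, file.path(rd, "trace.csv"), row.names = FALSE)
    kin <- corona_kinetics(trace)
    out$ring_absent <<- !is.finite(kin$T_star)
    jsonlite::write_json(
      list(T_star = kin$T_star, latency_bound = kin$latency_bound,
           v_i = kin$v_i, v_f = kin$v_f, ring_absent = out$ring_absent),
      file.path(rd, "kinetics.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  })

  if (ok && need("corona") && file.exists(file.path(rd, "kinetics.json"))) {
    out$kinetics <- jsonlite::read_json(file.path(rd, "kinetics.json"),
                                        simplifyVector = TRUE)
    out$ring_absent <- isTRUE(out$kinetics$ring_absent)
  }

  ok && try_stage("tracks", c("samples.csv", "directionality.csv"), function() {
    tk <- config$tracking
    t_start <- if (identical(tk$t_start, "mid"))
      config$frame_cadence * floor(t_end / 2 / config$frame_cadence)
    else tk$t_start
    times <- t_start + seq(0, tk$duration_min, by = 1 / tk$fps)
    s2 <- simulate_colony(params, sort(unique(c(0, times))))
    tp <- track_pipeline(s2, t_start, tk$duration_min, tk$fps)
    utils::write.csv(tp$samples, file.path(rd, "samples.csv"), row.names = FALSE)
    prof <- sliding_window_profile(tp$samples, n_min = tk$n_min)
    utils::write.csv(prof, file.path(rd, "directionality.csv"),
                     row.names = FALSE)
    ang <- step_headings(tp$samples)
    if (length(ang) >= 5) {
      vf <- vonmises_fit(ang, fix_mu = 0)
      jsonlite::write_json(list(mu = vf$mu, kappa = vf$kappa, n = vf$n),
                           file.path(rd, "vonmises.json"), auto_unbox = TRUE,
                           digits = NA)
    }
  })

  out
}
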