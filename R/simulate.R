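# Agent-based colony simulator. All positions are in um in a frame-centred
# coordinate system (the rendered frame spans [-W/2, W/2] on both axes,
# W = image_size * pixel_size). Times are in minutes.

STATE_LEVELS <- c("rounded", "elongated", "corona")

#' Prescribed ring radius in kinematic mode
#'
#' Continuous piecewise-linear trajectory: flat at `ring_start_radius` until
#' `ring_formation_time`, advancing at `ring_speed_initial` until
#' `speed_crossover_time` and at `ring_speed_late` thereafter.
#'
#' @param params a [colony_params()] object.
#' @param t time(s) in minutes.
#' @return ring radius (um) at each `t`.
#' @export
ring_radius_kinematic <- function(params, t) {
  tf <- params$ring_formation_time
  tc <- max(params$speed_crossover_time, tf)
  params$ring_start_radius +
    params$ring_speed_initial * pmax(0, pmin(t, tc) - tf) +
    params$ring_speed_late * pmax(0, t - tc)
}

# Prescribed ring speed at time t (kinematic mode).
ring_speed_kinematic <- function(params, t) {
  tf <- params$ring_formation_time
  tc <- max(params$speed_crossover_time, tf)
  ifelse(t < tf, 0, ifelse(t < tc, params$ring_speed_initial, params$ring_speed_late))
}

#' Seed the initial colony
#'
#' Places `n_cells` agents in a disc of `drop_radius` with a truncated
#' two-dimensional Gaussian areal density (sd `placement_sd_frac *
#' drop_radius`; radial coordinate therefore Rayleigh-distributed, angle
#' uniform): the expected density is a smooth dome decreasing monotonically
#' from the centre outwards, as in a freshly seeded drop. In `uniform` mode
#' agents are scattered uniformly over the full frame instead.
#'
#' @param params a [colony_params()] object; `params$seed` makes the
#'   placement deterministic.
#' @return an agent table at `t = 0`: data.frame with columns `id`, `t_min`,
#'   `x_um`, `y_um`, `state` (`rounded`/`elongated`/`corona`), `alive`.
#' @export
make_colony <- function(params) {
  validate_colony_params(params)
  set.seed(params$seed)
  n <- as.integer(params$n_cells)
  if (params$mode == "uniform") {
    half <- params$image_size * params$pixel_size / 2
    x <- stats::runif(n, -half, half)
    y <- stats::runif(n, -half, half)
  } else {
    sd <- params$placement_sd_frac * params$drop_radius
    # inverse-CDF sample of the Rayleigh radial law truncated at drop_radius
    u <- stats::runif(n)
    pmaxr <- 1 - exp(-params$drop_radius^2 / (2 * sd^2))
    r <- sd * sqrt(-2 * log(1 - u * pmaxr))
    ang <- stats::runif(n, -pi, pi)
    x <- r * cos(ang)
    y <- r * sin(ang)
  }
  st <- initial_states(params, x, y)
  data.frame(id = seq_len(n), t_min = 0, x_um = x, y_um = y,
             state = st, alive = TRUE, stringsAsFactors = FALSE)
}

initial_states <- function(params, x, y) {
  r <- sqrt(x^2 + y^2)
  if (params$mode == "kinematic") {
    ifelse(r < params$core_radius, "rounded", "elongated")
  } else {
    rep("elongated", length(x))  # mechanistic: fully oxygenated at t = 0
  }
}

#' Advance agents by one time step
#'
#' State rules: `rounded` agents do not move; `elongated` agents take a step
#' of length `base_speed * dt` with heading von Mises about the outward
#' radial direction (concentration `intermediate_kappa`, or `nc_bias_kappa`
#' in unconfined mode; 0 = unbiased); `corona` agents step at the corona
#' speed with heading von Mises(outward, `ring_kappa`). With
#' `division_rate > 0` each agent divides with probability
#' `division_rate * dt / 60`, duplicating in place under a fresh id.
#'
#' States are re-derived before stepping: in kinematic mode from the colony
#' geometry and cohort membership (`cohort` attribute, see
#' [simulate_colony()]); in mechanistic mode from the local oxygen
#' concentration in `field` (`< c_round`: rounded; `< c_crit`: corona;
#' otherwise elongated).
#'
#' @param agents agent table (one time point) as from [make_colony()].
#' @param field an `oxygen_field` (mechanistic mode) or `NULL`.
#' @param params a [colony_params()] object.
#' @param dt step (min).
#' @param t current time (min); needed in kinematic mode for the prescribed
#'   ring speed.
#' @param next_id first id to assign to daughters (default: max id + 1).
#' @return agent table at `t + dt` (same columns; possibly more rows).
#' @export
step_agents <- function(agents, field = NULL, params, dt = params$step_dt,
                        t = agents$t_min[1], next_id = NULL) {
  n <- nrow(agents)
  x <- agents$x_um; y <- agents$y_um
  r <- sqrt(x^2 + y^2)
  phi <- atan2(y, x)          # outward radial direction per agent
  phi[r == 0] <- stats::runif(sum(r == 0), -pi, pi)

  state <- derive_states(agents, field, params, t)

  speed <- numeric(n)
  kappa <- numeric(n)
  el <- state == "elongated"
  co <- state == "corona"
  speed[el] <- params$base_speed
  kappa[el] <- if (params$mode == "unconfined") params$nc_bias_kappa else params$intermediate_kappa
  if (any(co)) {
    cs <- params$corona_speed
    if (identical(cs, "auto")) {
      cs <- if (params$mode == "kinematic") {
        vr <- ring_speed_kinematic(params, t)
        a1 <- vm_a1(params$ring_kappa)
        if (a1 > 0) vr / a1 else params$base_speed
      } else params$base_speed
    }
    speed[co] <- cs
    kappa[co] <- if (params$mode == "mechanistic")
      params$oxygen$corona_kappa else params$ring_kappa
  }

  move <- speed > 0
  if (any(move)) {
    # draw heading offsets by distinct kappa values (vectorised per group)
    off <- numeric(n)
    for (k in unique(kappa[move])) {
      idx <- which(move & kappa == k)
      off[idx] <- rvonmises(length(idx), 0, k)
    }
    head <- phi + off
    x[move] <- x[move] + speed[move] * dt * cos(head[move])
    y[move] <- y[move] + speed[move] * dt * sin(head[move])
  }

  out <- data.frame(id = agents$id, t_min = t + dt, x_um = x, y_um = y,
                    state = state, alive = TRUE, stringsAsFactors = FALSE)

  if (params$division_rate > 0) {
    pdiv <- params$division_rate * dt / 60
    div <- stats::runif(n) < pdiv
    if (any(div)) {
      if (is.null(next_id)) next_id <- max(agents$id) + 1L
      kids <- out[div, , drop = FALSE]
      kids$id <- next_id + seq_len(nrow(kids)) - 1L
      out <- rbind(out, kids)
    }
  }
  attr(out, "cohort") <- attr(agents, "cohort")
  out
}

derive_states <- function(agents, field, params, t) {
  r <- sqrt(agents$x_um^2 + agents$y_um^2)
  n <- nrow(agents)
  if (params$mode == "uniform") return(rep("elongated", n))
  if (params$mode == "unconfined") return(rep("elongated", n))
  if (params$mode == "mechanistic") {
    if (is.null(field)) stop("mechanistic mode requires an oxygen field", call. = FALSE)
    conc <- oxygen_at(field, r)
    ox <- params$oxygen
    return(ifelse(conc < ox$c_round, "rounded",
                  ifelse(conc < ox$c_crit, "corona", "elongated")))
  }
  # kinematic: states are cell properties fixed at seeding (core cells stay
  # rounded, others elongated) -- re-deriving them from the current radius
  # would freeze any random-walker that strays into the core and pile cells
  # up at the core edge. The conserved cohort turns corona at formation.
  cohort <- attr(agents, "cohort")
  st <- agents$state
  if (!is.null(cohort) && t >= params$ring_formation_time) {
    st[agents$id %in% cohort] <- "corona"
  }
  st
}

#' Simulate a synthetic colony time-lapse
#'
#' Runs the agent model for `params$duration` hours in steps of
#' `params$step_dt` minutes and records agent snapshots at `frame_times`
#' (positions linearly interpolated inside a step, emulating the
#' minutes-scale heading persistence of the cells), the ground-truth ring
#' trajectory at every step, and (mechanistic mode) the radial oxygen field.
#' Frames are not rasterised here; pass the result to [render_frames()] or
#' [profile_series()].
#'
#' In kinematic mode the cells lying in the annulus
#' `ring_start_radius +/- ring_width_initial/2` at `ring_formation_time`
#' become the conserved corona cohort; their biased walk has mean radial
#' drift equal to the prescribed ring speed (see [colony_params()]).
#'
#' @param params a [colony_params()] object.
#' @param frame_times times (min) at which to record agent snapshots;
#'   default: every simulation step.
#' @return an object of class `colony_sim`: list with `params`, `agents`
#'   (snapshot table: id, t_min, x_um, y_um, state, alive), `ring`
#'   (data.frame t_min, R_um, present), `oxygen` (list of `oxygen_field`s at
#'   `frame_times`, mechanistic only), `frame_times`.
#' @examples
#' p <- colony_preset("uniform-motility", seed = 1, n_cells = 20, duration = 0.1)
#' sim <- simulate_colony(p)
#' head(sim$agents)
#' @export
simulate_colony <- function(params, frame_times = NULL) {
  validate_colony_params(params)
  t_end <- params$duration * 60
  dt <- params$step_dt
  steps <- seq(0, t_end, by = dt)
  if (is.null(frame_times)) frame_times <- steps
  frame_times <- sort(unique(frame_times))
  if (any(frame_times < 0 | frame_times > t_end + 1e-9))
    stop("frame_times must lie within the run duration", call. = FALSE)

  confined <- params$mode %in% c("kinematic", "mechanistic")
  if (params$mode == "kinematic" && t_end < params$ring_formation_time)
    warning("duration shorter than ring_formation_time: ring never forms")

  cur <- make_colony(params)   # also seeds the RNG
  next_id <- as.integer(params$n_cells) + 1L

  field <- NULL
  ox <- params$oxygen
  if (params$mode == "mechanistic") {
    field <- oxygen_field_init(ox$dr, ox$r_max)
    rho_ref <- NULL
  }

  snaps <- vector("list", length(frame_times))
  ox_out <- if (params$mode == "mechanistic") vector("list", length(frame_times)) else NULL
  ring_R <- numeric(length(steps)); ring_present <- logical(length(steps))

  record <- function(i, tab, tt) {
    tab$t_min <- tt
    snaps[[i]] <<- tab
    if (!is.null(ox_out)) ox_out[[i]] <<- field
  }

  fi <- 1L
  # snapshots exactly at t = 0
  while (fi <= length(frame_times) && frame_times[fi] <= 0 + 1e-9) {
    record(fi, cur, frame_times[fi]); fi <- fi + 1L
  }
  ring_R[1] <- if (params$mode == "kinematic") ring_radius_kinematic(params, 0) else NA_real_
  ring_present[1] <- FALSE

  for (k in seq_along(steps)[-1]) {
    t0 <- steps[k - 1]; t1 <- steps[k]

    if (params$mode == "mechanistic") {
      dens <- agent_radial_density(cur, field$r_um, ox$dr)
      if (is.null(rho_ref)) {
        sel <- field$r_um < 0.25 * params$drop_radius
        rho_ref <- mean(dens[sel])
      }
      rho <- dens / rho_ref
      dt_max <- ox$dr^2 / (4 * ox$diffusion)
      nsub <- ceiling(dt / (0.8 * dt_max))
      for (s in seq_len(nsub)) {
        field <- step_oxygen(field, rho, dt / nsub, ox$diffusion,
                             ox$consumption_rate, ox$km)
      }
    }

    # mark the kinematic cohort the first time formation time is reached
    if (params$mode == "kinematic" && is.null(attr(cur, "cohort")) &&
        t1 >= params$ring_formation_time) {
      r <- sqrt(cur$x_um^2 + cur$y_um^2)
      half <- params$ring_width_initial / 2
      band <- abs(r - params$ring_start_radius) <= half
      attr(cur, "cohort") <- cur$id[band]
    }

    prev <- cur
    cur <- step_agents(prev, field, params, dt, t = t0, next_id = next_id)
    if (nrow(cur) > nrow(prev)) next_id <- max(cur$id) + 1L

    # ground-truth ring
    if (params$mode == "kinematic") {
      ring_R[k] <- ring_radius_kinematic(params, t1)
      ring_present[k] <- t1 >= params$ring_formation_time
    } else if (params$mode == "mechanistic") {
      rc <- oxygen_contour(field, params$oxygen$c_crit)
      ring_R[k] <- rc
      ring_present[k] <- is.finite(rc) && any(cur$state == "corona")
    } else {
      ring_R[k] <- NA_real_; ring_present[k] <- FALSE
    }

    # interpolated snapshots in (t0, t1]
    while (fi <= length(frame_times) && frame_times[fi] <= t1 + 1e-9) {
      tt <- frame_times[fi]
      f <- (tt - t0) / dt
      tab <- cur
      np <- nrow(prev)
      tab$x_um[seq_len(np)] <- prev$x_um + f * (cur$x_um[seq_len(np)] - prev$x_um)
      tab$y_um[seq_len(np)] <- prev$y_um + f * (cur$y_um[seq_len(np)] - prev$y_um)
      record(fi, tab, tt); fi <- fi + 1L
    }
  }

  agents <- do.call(rbind, snaps)
  rownames(agents) <- NULL
  ring <- data.frame(t_min = steps, R_um = ring_R, present = ring_present)
  if (!confined) ring$R_um <- NA_real_

  structure(list(params = params, agents = agents, ring = ring,
                 oxygen = ox_out, frame_times = frame_times),
            class = "colony_sim")
}

#' @export
print.colony_sim <- function(x, ...) {
  cat("<colony_sim>", x$params$mode, "run,",
      length(x$frame_times), "snapshots,",
      length(unique(x$agents$id)), "agents, duration",
      x$params$duration, "h\n")
  invisible(x)
}

# Areal agent density per radial bin (counts / annulus area, 1/um^2).
agent_radial_density <- function(agents, r_centers, dr) {
  r <- sqrt(agents$x_um^2 + agents$y_um^2)
  edges <- c(r_centers - dr / 2, r_centers[length(r_centers)] + dr / 2)
  idx <- findInterval(r, edges, rightmost.closed = FALSE)
  idx[idx < 1 | idx > length(r_centers)] <- NA
  counts <- tabulate(idx, nbins = length(r_centers))
  area <- pi * (edges[-1]^2 - edges[-length(edges)]^2)
  counts / area
}

#' Extract one agent snapshot from a simulation
#'
#' @param sim a `colony_sim`.
#' @param t a recorded frame time (min).
#' @return the agent table at `t`.
#' @export
agents_at <- function(sim, t) {
  tol <- 1e-6
  sel <- abs(sim$agents$t_min - t) < tol
  if (!any(sel)) stop("no snapshot recorded at t = ", t, " min", call. = FALSE)
  sim$agents[sel, , drop = FALSE]
}
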