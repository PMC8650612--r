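# Single-cell tracking: nearest-neighbour frame-to-frame linking, per-minute
# velocity decomposition into radial and tangential parts, sliding-window
# radial motility profiles, spontaneous motility.

#' Link detections into tracks
#'
#' Frame-to-frame nearest-neighbour assignment: candidate pairs within the
#' search radius `max_speed * dt` are sorted globally by distance and
#' accepted greedily (deterministic conflict resolution); unmatched
#' detections start new tracks. No gap closing (memory 0).
#'
#' @param detections list of detection tables (`x_um`, `y_um`), one per
#'   frame (see [detect_spots()]), or a single data.frame with a `t_min`
#'   column to split on.
#' @param times frame times (min); inferred from `t_min` when `detections`
#'   is a single data.frame.
#' @param max_speed maximum cell speed (um/min) defining the search radius.
#' @return a `track_set` data.frame: `track_id`, `t_min`, `x_um`, `y_um`.
#' @export
link_tracks <- function(detections, times = NULL, max_speed = 10) {
  if (is.data.frame(detections)) {
    stopifnot("t_min" %in% names(detections))
    times <- sort(unique(detections$t_min))
    detections <- lapply(times, function(tt)
      detections[abs(detections$t_min - tt) < 1e-9, , drop = FALSE])
  }
  nf <- length(detections)
  if (nf < 2) stop("link_tracks: need at least 2 frames", call. = FALSE)
  stopifnot(length(times) == nf)

  track_of <- vector("list", nf)
  n1 <- nrow(detections[[1]])
  track_of[[1]] <- seq_len(n1)
  n_tracks <- n1
  for (k in 2:nf) {
    dt <- times[k] - times[k - 1]
    prev <- detections[[k - 1]]; cur <- detections[[k]]
    m <- link_frames_cpp(prev$x_um, prev$y_um, cur$x_um, cur$y_um,
                         max_speed * dt)
    ids <- integer(nrow(cur))
    linked <- m > 0
    ids[linked] <- track_of[[k - 1]][m[linked]]
    nnew <- sum(!linked)
    if (nnew > 0) {
      ids[!linked] <- n_tracks + seq_len(nnew)
      n_tracks <- n_tracks + nnew
    }
    track_of[[k]] <- ids
  }
  out <- do.call(rbind, lapply(seq_len(nf), function(k) {
    d <- detections[[k]]
    if (nrow(d) == 0)
      return(data.frame(track_id = integer(0), t_min = numeric(0),
                        x_um = numeric(0), y_um = numeric(0)))
    data.frame(track_id = track_of[[k]], t_min = times[k],
               x_um = d$x_um, y_um = d$y_um)
  }))
  out <- out[order(out$track_id, out$t_min), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("track_set", "data.frame")
  out
}

#' Per-interval velocity samples of a track set
#'
#' Walks each track in non-overlapping windows of `interval` minutes,
#' anchored to the absolute interval grid (a track that starts between grid
#' points contributes from the next grid point on, keeping all samples in
#' phase), and emits, per window, the
#' instantaneous speed `|v|`, the radial velocity component `v_r` (projection
#' on the outward unit vector from `center` at the window start) and their
#' ratio. The ratio is reported only when `|v| >= speed_floor`: the direction
#' of a near-zero step is noise. `|v_r| <= |v|` always.
#'
#' @param tracks a [link_tracks()] result (or any data.frame with
#'   `track_id`, `t_min`, `x_um`, `y_um`).
#' @param center colony centre `(x, y)` in um.
#' @param interval sampling interval (min).
#' @param speed_floor minimum speed (um/min) for a defined ratio.
#' @return data.frame: `track_id`, `t_min` (window start), `R_um` (radius at
#'   window start), `speed_um_min`, `v_r_um_min`, `v_t_um_min` (signed
#'   tangential component), `ratio`.
#' @export
velocity_samples <- function(tracks, center = c(0, 0), interval = 1,
                             speed_floor = 0.5) {
  sp <- split(tracks[, c("t_min", "x_um", "y_um")], tracks$track_id)
  rows <- lapply(names(sp), function(id) {
    d <- sp[[id]]
    d <- d[order(d$t_min), , drop = FALSE]
    if (nrow(d) < 2) return(NULL)
    # anchor sampling to the absolute interval grid: tracks that (re)start
    # between grid points contribute from the next grid point on, so all
    # samples across tracks stay in phase
    on_grid <- which(abs(d$t_min / interval - round(d$t_min / interval)) < 1e-6)
    if (length(on_grid) < 2) return(NULL)
    tg <- d$t_min[on_grid]
    consec <- which(abs(diff(tg) - interval) < 1e-6)
    if (length(consec) == 0) return(NULL)
    starts <- on_grid[consec]
    ends <- on_grid[consec + 1]
    x0 <- d$x_um[starts]; y0 <- d$y_um[starts]
    dx <- d$x_um[ends] - x0; dy <- d$y_um[ends] - y0
    rx <- x0 - center[1]; ry <- y0 - center[2]
    R <- sqrt(rx^2 + ry^2)
    speed <- sqrt(dx^2 + dy^2) / interval
    vr <- ifelse(R > 0, (dx * rx + dy * ry) / R / interval, NA_real_)
    vt <- ifelse(R > 0, (rx * dy - ry * dx) / R / interval, NA_real_)
    ratio <- ifelse(speed >= speed_floor & is.finite(vr), vr / speed, NA_real_)
    data.frame(track_id = as.integer(id), t_min = d$t_min[starts],
               R_um = R, speed_um_min = speed, v_r_um_min = vr,
               v_t_um_min = vt, ratio = ratio)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(track_id = integer(0), t_min = numeric(0),
                      R_um = numeric(0), speed_um_min = numeric(0),
                      v_r_um_min = numeric(0), v_t_um_min = numeric(0),
                      ratio = numeric(0))
  rownames(out) <- NULL
  out
}

#' Sliding-window radial motility profile
#'
#' Averages velocity samples in 150-um-wide radial windows slid in `step`
#' increments: `<|v|>(R)`, `<v_r>(R)` and the mean directionality ratio
#' `<v_r/|v|>(R)`. Windows with fewer than `n_min` samples are reported as
#' `NA`. For extremum statistics (a maximum over R, or the value at a given
#' radius) use a large `n_min` (~200): the mean of a handful of angular
#' samples is dominated by sampling noise.
#'
#' @param samples a [velocity_samples()] table.
#' @param window window width (um).
#' @param step grid step (um).
#' @param n_min minimum samples per window.
#' @return a `directionality_profile` data.frame: `R_um`, `mean_speed`,
#'   `mean_v_r`, `mean_ratio`, `n`, `n_ratio`.
#' @export
sliding_window_profile <- function(samples, window = 150, step = 25,
                                   n_min = 20) {
  stopifnot(nrow(samples) > 0)
  grid <- seq(floor(min(samples$R_um) / step) * step,
              max(samples$R_um), by = step)
  rows <- lapply(grid, function(Rc) {
    sel <- samples$R_um >= Rc - window / 2 & samples$R_um < Rc + window / 2
    n <- sum(sel)
    if (n < n_min)
      return(data.frame(R_um = Rc, mean_speed = NA_real_, mean_v_r = NA_real_,
                        mean_ratio = NA_real_, n = n, n_ratio = 0L))
    rat <- samples$ratio[sel]
    data.frame(R_um = Rc,
               mean_speed = mean(samples$speed_um_min[sel]),
               mean_v_r = mean(samples$v_r_um_min[sel], na.rm = TRUE),
               mean_ratio = if (sum(is.finite(rat)) >= n_min)
                 mean(rat, na.rm = TRUE) else NA_real_,
               n = n, n_ratio = sum(is.finite(rat)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("directionality_profile", "data.frame")
  out
}

#' Value of a directionality profile at a radius
#'
#' Linear interpolation of `mean_ratio` over the defined windows.
#'
#' @param profile a [sliding_window_profile()] result.
#' @param R radius (um).
#' @return interpolated `<v_r/|v|>` at `R`.
#' @export
profile_ratio_at <- function(profile, R) {
  ok <- is.finite(profile$mean_ratio)
  if (!any(ok)) return(NA_real_)
  stats::approx(profile$R_um[ok], profile$mean_ratio[ok], xout = R, rule = 2)$y
}

#' Spontaneous motility
#'
#' Mean per-interval instantaneous speed over all tracks, used on uniformly
#' seeded (unconfined, unbiased) runs to quantify baseline random motility.
#'
#' @param tracks a [link_tracks()] result.
#' @param interval sampling interval (min).
#' @return mean speed (um/min).
#' @export
spontaneous_motility <- function(tracks, interval = 1) {
  vs <- velocity_samples(tracks, center = c(0, 0), interval = interval,
                         speed_floor = 0)
  if (nrow(vs) == 0) stop("spontaneous_motility: no velocity samples", call. = FALSE)
  mean(vs$speed_um_min)
}

#' Step headings relative to the outward radial direction
#'
#' Angle of each per-interval displacement measured from the outward radial
#' unit vector at the window start, in `(-pi, pi]`; 0 means radially
#' outward. These are the angles fitted by [vonmises_fit()] (with
#' `fix_mu = 0`, kappa measures the accuracy of radial orientation).
#'
#' @param samples a [velocity_samples()] table.
#' @param speed_floor exclude near-stationary steps (um/min).
#' @return numeric vector of angles (rad).
#' @export
step_headings <- function(samples, speed_floor = 0.5) {
  sel <- is.finite(samples$v_r_um_min) & is.finite(samples$v_t_um_min) &
    samples$speed_um_min >= speed_floor
  atan2(samples$v_t_um_min[sel], samples$v_r_um_min[sel])
}
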