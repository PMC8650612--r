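# Corona (ring) detection in radial-profile series and its kinetics:
# formation time T*, displacement, initial and late propagation speeds,
# ring width/density dynamics and the area-conservation width model.

# centred moving average with windows clamped to the series ends
moving_average <- function(v, width) {
  if (width <= 1) return(v)
  n <- length(v)
  h <- floor(width / 2)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# prominence of a local maximum at index i: height above the higher of the
# two bases (minimum between the peak and the nearest strictly higher value,
# or the series end, on each side)
peak_prominence <- function(v, i) {
  n <- length(v)
  lmin <- v[i]; j <- i - 1
  while (j >= 1 && v[j] <= v[i]) { lmin <- min(lmin, v[j]); j <- j - 1 }
  rmin <- v[i]; j <- i + 1
  while (j <= n && v[j] <= v[i]) { rmin <- min(rmin, v[j]); j <- j + 1 }
  v[i] - max(lmin, rmin)
}

#' Detect the corona in one radial profile
#'
#' After moving-average smoothing, returns the radius of the outermost local
#' density maximum that lies beyond `peripheral_fraction` of the colony
#' radius and whose prominence exceeds a noise floor. The floor is the
#' largest of three terms: twice the sd of first differences over the
#' outermost run of empty annuli (relative density < 1); an absolute minimum
#' of `min_prominence` density percent (an arbitrarily quiet background must
#' not promote noise bumps); and `z_counting` binomial standard errors of
#' the smoothed peak estimate, `z * 100 * sqrt(p(1-p)/n_px) / sqrt(w)` --
#' density fluctuations of the cell field itself are static, so they recur
#' frame after frame and cannot be removed by the persistence filter; they
#' must be rejected statistically. Absence of a corona is a value (`NA`), not an error.
#'
#' @param profile a [radial_profile()].
#' @param smooth_width moving-average width (bins).
#' @param peripheral_fraction a peak counts as peripheral when its radius
#'   exceeds this fraction of the colony radius (outermost radius with
#'   smoothed density >= `colony_floor`).
#' @param min_prominence absolute prominence floor (density %).
#' @param z_counting multiplier on the binomial (counting) standard error of
#'   the smoothed peak density.
#' @param colony_floor density (%) defining the colony extent.
#' @param min_completeness annuli clipped by the frame boundary to below
#'   this fraction of their nominal area (corner bins beyond the inscribed
#'   circle) are excluded: their density estimates rest on too few pixels
#'   to support peak detection.
#' @return ring radius `R_peak` (um), or `NA_real_` when no corona is
#'   present; attribute `prominence` carries the peak prominence.
#' @export
detect_corona <- function(profile, smooth_width = 3, peripheral_fraction = 0.5,
                          min_prominence = 0.5, z_counting = 6,
                          colony_floor = 2, min_completeness = 0.9) {
  stopifnot(inherits(profile, "radial_profile"))
  if (nrow(profile) < 5)
    stop("detect_corona: need at least 5 radial bins", call. = FALSE)
  ps <- attr(profile, "pixel_size")
  if (!is.null(ps)) {
    bw <- attr(profile, "bin_width")
    nominal <- 2 * pi * profile$bin_center_um * bw / ps^2
    profile <- profile[profile$n_px >= min_completeness * nominal |
                         profile$bin_center_um < bw, , drop = FALSE]
    if (nrow(profile) < 5) return(NA_real_)
  }
  r <- profile$bin_center_um
  v <- moving_average(profile$relative_density, smooth_width)
  n <- length(v)

  occupied <- which(v >= colony_floor)
  if (length(occupied) == 0) return(NA_real_)
  colony_radius <- r[max(occupied)]

  # noise floor from the outermost contiguous run of empty annuli
  floor_prom <- min_prominence
  empty <- profile$relative_density < 1
  if (empty[n]) {
    j <- n
    while (j >= 1 && empty[j]) j <- j - 1
    run <- (j + 1):n
    if (length(run) >= 5)
      floor_prom <- max(min_prominence,
                        2 * stats::sd(diff(profile$relative_density[run])))
  }

  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  cand <- which(is_max & r > peripheral_fraction * colony_radius)
  if (length(cand) == 0) return(NA_real_)
  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  p_hat <- pmin(pmax(v[cand] / 100, 0), 1)
  counting_se <- 100 * sqrt(p_hat * (1 - p_hat) / profile$n_px[cand]) /
    sqrt(smooth_width)
  ok <- prom > pmax(floor_prom, z_counting * counting_se)
  if (!any(ok)) return(NA_real_)
  pick <- max(cand[ok])
  prom_pick <- prom[which(cand == pick)]
  # sub-bin refinement: density-weighted centroid of the contiguous region
  # above half the peak's prominence (argmax alone wanders over the broad,
  # flat-topped bump the ring produces at low density)
  cutoff <- v[pick] - 0.5 * prom_pick
  lo <- pick; while (lo > 1 && v[lo - 1] >= cutoff) lo <- lo - 1
  hi <- pick; while (hi < n && v[hi + 1] >= cutoff) hi <- hi + 1
  w <- v[lo:hi] - cutoff
  R_peak <- sum(r[lo:hi] * w) / sum(w)
  structure(R_peak, prominence = prom_pick)
}

#' Build a corona trace from a profile series
#'
#' Applies [detect_corona()] to each profile and assembles the time series
#' of ring radius and presence. Because the detector picks the outermost
#' qualifying peak frame by frame, an isolated detection failure can latch
#' onto an interior density feature thousands of micrometres away; frames
#' whose radius deviates from a 5-point running median of the detected
#' series by more than `max_jump` are therefore marked absent (the ring
#' cannot physically jump between consecutive frames).
#'
#' @param profiles list of [radial_profile()]s (each carrying its `t_min`).
#' @param max_jump outlier threshold (um) against the running median;
#'   `Inf` disables the filter.
#' @param ... passed to [detect_corona()].
#' @return a `corona_trace`: data.frame with `t_min`, `R_um`, `present`.
#' @export
corona_trace <- function(profiles, max_jump = 150, ...) {
  t <- vapply(profiles, function(p) attr(p, "t_min"), numeric(1))
  R <- vapply(profiles, function(p) as.numeric(detect_corona(p, ...)), numeric(1))
  out <- data.frame(t_min = t, R_um = R, present = is.finite(R))
  out <- out[order(out$t_min), , drop = FALSE]
  rownames(out) <- NULL
  if (is.finite(max_jump) && sum(out$present) >= 5) {
    idx <- which(out$present)
    ref <- stats::runmed(out$R_um[idx], 5, endrule = "median")
    bad <- abs(out$R_um[idx] - ref) > max_jump
    out$present[idx[bad]] <- FALSE
    out$R_um[idx[bad]] <- NA_real_
  }
  class(out) <- c("corona_trace", "data.frame")
  out
}

#' Corona formation time
#'
#' Earliest time at which the corona is detected in `persistence`
#' consecutive frames (flicker suppression), measured from the start of the
#' trace (confinement). The detection latency bound (persistence x frame
#' interval) is attached as an attribute and should be quoted with T*.
#'
#' @param trace a [corona_trace()].
#' @param persistence required consecutive detections (frames).
#' @return `T_star` (min), or `NA_real_` if the ring is never persistently
#'   detected; attribute `latency_bound` (min).
#' @export
formation_time <- function(trace, persistence = 3) {
  stopifnot(persistence >= 1)
  p <- trace$present
  n <- length(p)
  if (n >= persistence) {
    run <- stats::filter(as.numeric(p), rep(1, persistence), sides = 1)
    hit <- which(run == persistence)
    if (length(hit) > 0) {
      i <- hit[1] - persistence + 1
      dtf <- stats::median(diff(trace$t_min))
      return(structure(trace$t_min[i], latency_bound = persistence * dtf))
    }
  }
  structure(NA_real_, latency_bound = NA_real_)
}

#' Initial corona propagation speed
#'
#' Mean of the per-interval velocities of the detected ring radius over the
#' window `[T*, T* + window]` (for uniformly sampled traces this equals the
#' net displacement over the realised span divided by that span).
#'
#' @param trace a [corona_trace()].
#' @param t_star formation time (min); default [formation_time()] of the
#'   trace.
#' @param window averaging window after formation (min). The default 140 min
#'   follows the reported early-phase measurement window; a 120-min
#'   ("first 2 h") convention is also in circulation — set `window = 120`
#'   to use it.
#' @return `v_i` (um/min).
#' @export
initial_speed <- function(trace, t_star = NULL, window = 140) {
  if (is.null(t_star)) t_star <- as.numeric(formation_time(trace))
  if (!is.finite(t_star)) stop("initial_speed: no formation time", call. = FALSE)
  sel <- trace$present & trace$t_min >= t_star - 1e-9 &
    trace$t_min <= t_star + window + 1e-9
  d <- trace[sel, , drop = FALSE]
  if (nrow(d) < 2)
    stop("initial_speed: fewer than 2 detected frames in the window", call. = FALSE)
  mean(diff(d$R_um) / diff(d$t_min))
}

#' Late (constant-velocity) corona speed
#'
#' Ordinary least-squares slope of ring radius versus time over a late
#' window in which the displacement grows linearly.
#'
#' @param trace a [corona_trace()].
#' @param t_from,t_to window (min); default 10--24 h.
#' @return `v_f` (um/min); attributes `n` and `residual_sd`.
#' @export
late_speed <- function(trace, t_from = 600, t_to = 1440) {
  sel <- trace$present & trace$t_min >= t_from - 1e-9 & trace$t_min <= t_to + 1e-9
  d <- trace[sel, , drop = FALSE]
  if (nrow(d) < 5)
    stop("late_speed: fewer than 5 detected frames in the window", call. = FALSE)
  fit <- stats::lm(R_um ~ t_min, data = d)
  structure(unname(stats::coef(fit)[2]),
            n = nrow(d), residual_sd = stats::sd(stats::resid(fit)))
}

#' Ring displacement and kinetics summary
#'
#' Convenience wrapper: formation time, displacement
#' `dR(t) = R(t) - R(T*)`, initial and late speeds with their windows.
#'
#' @param trace a [corona_trace()].
#' @param persistence frames for [formation_time()].
#' @param vi_window window for [initial_speed()] (min).
#' @param vf_from,vf_to window for [late_speed()] (min).
#' @return a `kinetics_summary` list: `T_star`, `latency_bound`, `v_i`,
#'   `v_f`, `v_f_residual_sd`, `windows`, `displacement` (data.frame).
#' @export
corona_kinetics <- function(trace, persistence = 3, vi_window = 140,
                            vf_from = 600, vf_to = 1440) {
  ts <- formation_time(trace, persistence)
  out <- list(T_star = as.numeric(ts),
              latency_bound = attr(ts, "latency_bound"),
              v_i = NA_real_, v_f = NA_real_, v_f_residual_sd = NA_real_,
              windows = list(vi = vi_window, vf = c(vf_from, vf_to)),
              displacement = NULL)
  if (is.finite(out$T_star)) {
    R0 <- trace$R_um[trace$present & abs(trace$t_min - out$T_star) < 1e-9][1]
    disp <- trace[trace$present, c("t_min", "R_um")]
    disp$dR_um <- disp$R_um - R0
    out$displacement <- disp
    out$v_i <- tryCatch(initial_speed(trace, out$T_star, vi_window),
                        error = function(e) NA_real_)
    vf <- tryCatch(late_speed(trace, vf_from, vf_to), error = function(e) NA_real_)
    out$v_f <- as.numeric(vf)
    out$v_f_residual_sd <- attr(vf, "residual_sd")
  }
  class(out) <- "kinetics_summary"
  out
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf("<kinetics_summary> T* = %s min (latency <= %s), v_i = %s um/min, v_f = %s um/min\n",
              format(x$T_star), format(x$latency_bound),
              format(round(x$v_i, 3)), format(round(x$v_f, 3))))
  invisible(x)
}

#' Ring width and density over time
#'
#' For each frame with a detected ring, the ring extent is the contiguous
#' radial interval around the density peak where the (smoothed) relative
#' density stays at or above a floor; its length is the width `L(t)` and the
#' mean density over it is the ring density. The series is then resampled to
#' a regular reporting cadence and binned (mean +/- sd per group), following
#' the 6-min / 5-measurement convention of the ring-feature measurements.
#'
#' @param profiles list of [radial_profile()]s.
#' @param trace matching [corona_trace()].
#' @param density_floor absolute floor (density %), or `"auto"`: baseline
#'   plus half the peak height above the intermediate-zone baseline (minimum
#'   density between 30% and 90% of the ring radius).
#' @param smooth_width moving-average width (bins).
#' @param cadence reporting cadence (min).
#' @param group measurements per reported point.
#' @return list with `per_frame` (data.frame `t_min`, `width_um`,
#'   `density_pct`, `flagged`) and `binned` (data.frame of group means and
#'   sds).
#' @export
ring_geometry <- function(profiles, trace, density_floor = "auto",
                          smooth_width = 3, cadence = 6, group = 5) {
  pt <- vapply(profiles, function(p) attr(p, "t_min"), numeric(1))
  rows <- lapply(seq_along(profiles), function(k) {
    tr <- trace[abs(trace$t_min - pt[k]) < 1e-9, , drop = FALSE]
    if (nrow(tr) == 0 || !tr$present[1]) return(NULL)
    p <- profiles[[k]]
    r <- p$bin_center_um
    v <- moving_average(p$relative_density, smooth_width)
    bw <- attr(p, "bin_width")
    i <- which.min(abs(r - tr$R_um[1]))
    if (identical(density_floor, "auto")) {
      zone <- r >= 0.3 * r[i] & r < 0.9 * r[i]
      base <- if (any(zone)) min(v[zone]) else 0
      fl <- base + 0.5 * (v[i] - base)
    } else fl <- density_floor
    if (v[i] < fl)
      return(data.frame(t_min = pt[k], width_um = 0, density_pct = NA_real_,
                        flagged = TRUE))
    lo <- i; while (lo > 1 && v[lo - 1] >= fl) lo <- lo - 1
    hi <- i; while (hi < length(v) && v[hi + 1] >= fl) hi <- hi + 1
    data.frame(t_min = pt[k], width_um = (hi - lo + 1) * bw,
               density_pct = mean(v[lo:hi]), flagged = FALSE)
  })
  per_frame <- do.call(rbind, rows)
  binned <- NULL
  if (!is.null(per_frame) && nrow(per_frame) > 0) {
    ok <- per_frame[!per_frame$flagged, , drop = FALSE]
    if (nrow(ok) > 0) {
      grid <- seq(min(ok$t_min), max(ok$t_min), by = cadence)
      res <- data.frame(
        t_min = grid,
        width_um = stats::approx(ok$t_min, ok$width_um, grid, rule = 2)$y,
        density_pct = stats::approx(ok$t_min, ok$density_pct, grid, rule = 2)$y
      )
      g <- (seq_len(nrow(res)) - 1) %/% group
      agg <- function(x, f) as.numeric(tapply(x, g, f))
      sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
      binned <- data.frame(
        t_min = agg(res$t_min, mean),
        width_um = agg(res$width_um, mean),
        width_sd = agg(res$width_um, sd0),
        density_pct = agg(res$density_pct, mean),
        density_sd = agg(res$density_pct, sd0)
      )
    }
  }
  list(per_frame = per_frame, binned = binned)
}

#' Area-conserving ring width model
#'
#' A circular ring that conserves its cell number and density while its
#' radius grows must thin as `L(t) = L0 * R0 / R(t)`, keeping the product
#' `R * L` constant.
#'
#' @param L0 initial width (um).
#' @param R0 initial radius (um).
#' @param R_t ring radius series (um), all > 0.
#' @param times optional times (min) carried into the result.
#' @return a `ring_model_prediction` data.frame: `R_um`, `width_um`,
#'   `RL_um2` (constant), plus `t_min` when `times` given.
#' @export
ring_width_model <- function(L0, R0, R_t, times = NULL) {
  if (L0 <= 0 || R0 <= 0 || any(R_t <= 0))
    stop("ring_width_model: radii and width must be positive", call. = FALSE)
  out <- data.frame(R_um = R_t, width_um = L0 * R0 / R_t, RL_um2 = R_t * (L0 * R0 / R_t))
  if (!is.null(times)) out <- cbind(t_min = times, out)
  class(out) <- c("ring_model_prediction", "data.frame")
  out
}
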