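# Unconfined-colony expansion velocity (threshold-sweep border displacement)
# and the sector-count duplication estimator.

# outermost radius at which the profile stays >= th, with sub-bin linear
# interpolation of the crossing (NA when never attained)
border_radius <- function(profile, th, smooth_width = 3) {
  r <- profile$bin_center_um
  v <- moving_average(profile$relative_density, smooth_width)
  at <- which(v >= th)
  if (length(at) == 0) return(NA_real_)
  i <- max(at)
  if (i == length(v)) return(r[i])
  r[i] + (v[i] - th) / (v[i] - v[i + 1]) * (r[i + 1] - r[i])
}

#' Expansion velocity of an unconfined colony
#'
#' For each density threshold, the colony border is the outermost radius at
#' which the radial profile reaches the threshold; instantaneous border
#' velocities over a `lapse`-minute time-lapse are averaged over time, and
#' the per-threshold means are averaged over the threshold sweep. Because
#' the threshold choice is arbitrary, a range of values is used by default:
#' 10% to 50% of the central density of the first profile, in steps of 5%.
#'
#' @param profiles list of [radial_profile()]s from an unconfined run
#'   (typically the first 5 h).
#' @param thresholds absolute density thresholds (%), or `NULL` for the
#'   default sweep.
#' @param lapse time-lapse between compared frames (min).
#' @param smooth_width profile smoothing (bins) before border location.
#' @return an `expansion_estimate`: list with `v_NC` (um/min, mean over
#'   thresholds of per-threshold mean velocities), `per_threshold`
#'   (data.frame `threshold_pct`, `v_um_min`), `thresholds_dropped`.
#' @export
expansion_velocity <- function(profiles, thresholds = NULL, lapse = 1,
                               smooth_width = 3) {
  t <- vapply(profiles, function(p) attr(p, "t_min"), numeric(1))
  ord <- order(t)
  profiles <- profiles[ord]; t <- t[ord]
  if (length(profiles) < 2)
    stop("expansion_velocity: need at least 2 frames", call. = FALSE)
  if (is.null(thresholds)) {
    p0 <- profiles[[1]]
    central <- mean(moving_average(p0$relative_density, smooth_width)[
      p0$bin_center_um <= 5 * attr(p0, "bin_width")])
    thresholds <- seq(0.10, 0.50, by = 0.05) * central
  }
  dropped <- numeric(0)
  per <- lapply(thresholds, function(th) {
    b <- vapply(profiles, border_radius, numeric(1), th = th,
                smooth_width = smooth_width)
    if (all(!is.finite(b))) return(NA_real_)
    # pair frames `lapse` minutes apart
    vs <- numeric(0)
    for (i in seq_along(t)) {
      j <- which(abs(t - (t[i] + lapse)) < 1e-6)
      if (length(j) == 1 && is.finite(b[i]) && is.finite(b[j]))
        vs <- c(vs, (b[j] - b[i]) / lapse)
    }
    if (length(vs) == 0) return(NA_real_)
    mean(vs)
  })
  per <- unlist(per)
  bad <- !is.finite(per)
  if (any(bad)) {
    warning(sum(bad), " threshold(s) never attained; dropped")
    dropped <- thresholds[bad]
  }
  keep <- is.finite(per)
  if (!any(keep)) stop("expansion_velocity: no threshold attained", call. = FALSE)
  structure(list(
    v_NC = mean(per[keep]),
    per_threshold = data.frame(threshold_pct = thresholds[keep],
                               v_um_min = per[keep]),
    thresholds_dropped = dropped
  ), class = "expansion_estimate")
}

#' @export
print.expansion_estimate <- function(x, ...) {
  cat(sprintf("<expansion_estimate> v_NC = %.3f um/min over %d thresholds (sd %.3f)\n",
              x$v_NC, nrow(x$per_threshold), stats::sd(x$per_threshold$v_um_min)))
  invisible(x)
}

#' Duplication ratio from a fixed circular sector
#'
#' Counts detections inside a fixed circular sector over time; by symmetry
#' the expected net flux of cells through the sector is zero, so growth of
#' the count can only come from division. Counts are reported as a ratio to
#' the count at a reference time.
#'
#' @param detections list of detection tables (`x_um`, `y_um`), one per
#'   frame, e.g. from [detect_spots()].
#' @param times frame times (min).
#' @param sector list with `theta` (angle range, rad, in `(-pi, pi]`) and
#'   `r` (radius range, um); half-open on the upper edges.
#' @param reference_time time whose count defines `N0` (default: 600 min,
#'   i.e. 10 h after confinement); the nearest frame is used.
#' @return a `duplication_series` data.frame: `t_min`, `n`, `ratio`.
#' @export
duplication_estimate <- function(detections, times,
                                 sector = list(theta = c(-pi / 8, pi / 8),
                                               r = c(0, Inf)),
                                 reference_time = 600) {
  stopifnot(length(detections) == length(times))
  count_sector <- function(d) {
    if (nrow(d) == 0) return(0L)
    th <- atan2(d$y_um, d$x_um)
    r <- sqrt(d$x_um^2 + d$y_um^2)
    sum(th >= sector$theta[1] & th < sector$theta[2] &
          r >= sector$r[1] & r < sector$r[2])
  }
  n <- vapply(detections, count_sector, integer(1))
  iref <- which.min(abs(times - reference_time))
  if (n[iref] == 0)
    stop("duplication_estimate: no detections in the sector at the reference time",
         call. = FALSE)
  out <- data.frame(t_min = times, n = n, ratio = n / n[iref])
  class(out) <- c("duplication_series", "data.frame")
  out
}
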