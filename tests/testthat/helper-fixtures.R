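# Shared fixture builders: everything is generated in code at test time.

# tiny confined kinematic colony for fast pipeline tests
tiny_kinematic <- function(seed = 1, ...) {
  base <- list(mode = "kinematic", n_cells = 400, drop_radius = 600,
               core_radius = 300, ring_start_radius = 475,
               ring_width_initial = 150, ring_formation_time = 30,
               ring_speed_initial = 2.2, ring_speed_late = 0.67,
               speed_crossover_time = 120, duration = 4,
               pixel_size = 6, image_size = 512, seed = seed)
  do.call(colony_params, utils::modifyList(base, list(...)))
}

# a binary_frame built directly from a logical matrix
bf_from_mask <- function(mask, pixel_size = 2, time = 0) {
  structure(list(mask = mask, pixel_size = pixel_size, t_min = time),
            class = "binary_frame")
}

# radial profile object built directly from values (complete annuli)
profile_from_values <- function(values, bin_width = 30, time = 0,
                                n_px = 10000) {
  structure(
    data.frame(bin_center_um = (seq_along(values) - 0.5) * bin_width,
               relative_density = values,
               n_px = rep_len(n_px, length(values))),
    center = c(0, 0), t_min = time, bin_width = bin_width,
    class = c("radial_profile", "data.frame"))
}

# ground-truth agent snapshots -> track_set (bypasses imaging)
tracks_from_agents <- function(sim, t_from = 0, t_to = Inf) {
  a <- sim$agents
  a <- a[a$t_min >= t_from & a$t_min <= t_to, ]
  out <- data.frame(track_id = a$id, t_min = a$t_min,
                    x_um = a$x_um, y_um = a$y_um)
  class(out) <- c("track_set", "data.frame")
  out
}

# place k points with minimum pairwise separation inside a square
place_separated <- function(k, half, min_sep, seed = 1) {
  set.seed(seed)
  pts <- matrix(numeric(0), ncol = 2)
  while (nrow(pts) < k) {
    cand <- runif(2, -half, half)
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) > min_sep)
      pts <- rbind(pts, cand)
  }
  data.frame(x_um = pts[, 1], y_um = pts[, 2])
}

# exact-likelihood grid-search oracle for the fixed-mean von Mises fit
vm_grid_oracle <- function(angles, mu = 0, grid = seq(0.01, 20, by = 0.01)) {
  ll <- vapply(grid, function(k)
    k * sum(cos(angles - mu)) -
      length(angles) * (log(2 * pi) +
                          log(besselI(k, 0, expon.scaled = TRUE)) + k),
    numeric(1))
  grid[which.max(ll)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
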