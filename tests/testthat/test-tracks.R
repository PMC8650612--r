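# Linking, velocity decomposition, sliding-window profiles, von Mises fits,
# spontaneous motility.

test_that("link_tracks: translating blob stays one track; distant blobs never swap", {
  times <- seq(0, 5, by = 1)
  det <- lapply(times, function(tt)
    data.frame(x_um = 3 * tt, y_um = 0))
  tr <- link_tracks(det, times, max_speed = 10)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), length(times))

  det2 <- lapply(times, function(tt)
    data.frame(x_um = c(3 * tt, 500 + 3 * tt), y_um = c(0, 0)))
  tr2 <- link_tracks(det2, times, max_speed = 10)
  expect_equal(length(unique(tr2$track_id)), 2)
  byid <- split(tr2$x_um, tr2$track_id)
  expect_true(all(vapply(byid, function(x) all(diff(x) == 3), logical(1))))
})

test_that("linking agrees with ground-truth identities on a uniform-motility run", {
  p <- colony_params(mode = "uniform", n_cells = 300, base_speed = 3.9,
                     duration = 0.5, pixel_size = 2, image_size = 1024, seed = 5)
  times <- seq(0, 10, by = 1 / 3)
  sim <- simulate_colony(p, times)
  dets <- lapply(times, function(tt) {
    a <- agents_at(sim, tt)
    a <- a[sample(nrow(a)), ]               # shuffle detection order
    data.frame(x_um = a$x_um, y_um = a$y_um, gt = a$id)
  })
  set.seed(2)
  tr <- link_tracks(lapply(dets, function(d) d[, c("x_um", "y_um")]),
                    times, max_speed = 10)
  # attach ground truth by frame order and position
  agree <- 0L; total <- 0L
  tr$gt <- NA_integer_
  for (k in seq_along(times)) {
    sel <- tr$t_min == times[k]
    tr_k <- tr[sel, ]
    m <- match(paste(round(tr_k$x_um, 6), round(tr_k$y_um, 6)),
               paste(round(dets[[k]]$x_um, 6), round(dets[[k]]$y_um, 6)))
    tr$gt[sel] <- dets[[k]]$gt[m]
  }
  for (id in unique(tr$track_id)) {
    g <- tr$gt[tr$track_id == id]
    if (length(g) < 2) next
    agree <- agree + sum(g[-1] == g[-length(g)])
    total <- total + length(g) - 1
  }
  expect_gte(agree / total, 0.95)
  # displacement bound respected by construction
  vs <- velocity_samples(tr, interval = 1 / 3, speed_floor = 0)
  expect_true(all(vs$speed_um_min <= 10 + 1e-9))
})

test_that("velocity_samples decomposes steps exactly", {
  mk <- function(x0, y0, x1, y1) {
    d <- data.frame(track_id = 1L, t_min = c(0, 1),
                    x_um = c(x0, x1), y_um = c(y0, y1))
    class(d) <- c("track_set", "data.frame"); d
  }
  out <- velocity_samples(mk(100, 0, 104, 0), center = c(0, 0))
  expect_equal(out$speed_um_min, 4)
  expect_equal(out$v_r_um_min, 4)
  expect_equal(out$ratio, 1)
  tang <- velocity_samples(mk(100, 0, 100, 4), center = c(0, 0))
  expect_equal(tang$v_r_um_min, 0)
  expect_equal(tang$ratio, 0)
  expect_equal(tang$v_t_um_min, 4)
  inward <- velocity_samples(mk(100, 0, 96, 0), center = c(0, 0))
  expect_equal(inward$ratio, -1)
  # below the speed floor the ratio is undefined
  slow <- velocity_samples(mk(100, 0, 100.2, 0), center = c(0, 0),
                           speed_floor = 0.5)
  expect_true(is.na(slow$ratio))
  expect_equal(slow$speed_um_min, 0.2)
})

test_that("|v_r| <= |v| on every sample of a full pipeline", {
  p <- colony_preset("uniform-motility", seed = 3, n_cells = 120,
                     image_size = 512, duration = 0.2)
  times <- seq(0, 10, by = 1 / 3)
  sim <- simulate_colony(p, times)
  tp <- track_pipeline(sim, 0, 10, 3)
  expect_gt(nrow(tp$samples), 100)
  ok <- is.finite(tp$samples$v_r_um_min)
  expect_true(all(abs(tp$samples$v_r_um_min[ok]) <=
                    tp$samples$speed_um_min[ok] + 1e-9))
})

test_that("sliding_window_profile: constants, sharp mixtures, n_min gating", {
  s1 <- data.frame(track_id = 1, t_min = 1, R_um = rep(500, 100),
                   speed_um_min = 3, v_r_um_min = 1.5, v_t_um_min = 0,
                   ratio = 0.5)
  pr <- sliding_window_profile(s1, n_min = 20)
  ok <- is.finite(pr$mean_ratio)
  expect_true(all(abs(pr$mean_ratio[ok] - 0.5) < 1e-12))
  expect_true(all(abs(pr$mean_speed[ok] - 3) < 1e-12))

  set.seed(7)
  R <- runif(4000, 1200, 2200)
  s2 <- data.frame(track_id = 1, t_min = 1, R_um = R, speed_um_min = 3,
                   v_r_um_min = ifelse(R > 1700, 3, 0), v_t_um_min = 0,
                   ratio = ifelse(R > 1700, 1, 0))
  pr2 <- sliding_window_profile(s2, window = 150, step = 25, n_min = 20)
  expect_true(all(pr2$mean_ratio[pr2$R_um >= 1800 & pr2$R_um < 2100] > 0.99))
  expect_true(all(pr2$mean_ratio[pr2$R_um > 1300 & pr2$R_um <= 1600] < 0.01))
  mid <- pr2$mean_ratio[pr2$R_um > 1650 & pr2$R_um < 1750]
  expect_true(all(mid > 0.05 & mid < 0.95))
  # windows below n_min are undefined
  s3 <- s1[1:10, ]
  pr3 <- sliding_window_profile(s3, n_min = 20)
  expect_true(all(!is.finite(pr3$mean_ratio)))
})

test_that("vonmises_fit: uniform limit, boundary MLE, cap flag and input checks", {
  set.seed(11)
  th <- runif(1e4, -pi, pi)
  f <- vonmises_fit(th)
  expect_lt(f$kappa, 0.05)
  # fixed mean with non-positive mean cosine: boundary kappa = 0
  f0 <- vonmises_fit(c(pi, pi, -pi / 2, pi / 2, pi * 0.9, -pi * 0.9),
                     fix_mu = 0)
  expect_equal(f0$kappa, 0)
  # identical angles hit the cap, flagged
  fc <- vonmises_fit(rep(0.3, 10))
  expect_equal(fc$kappa, 500)
  expect_true(fc$at_cap)
  expect_error(vonmises_fit(c(0.1, 0.2)), "at least 5")
})

test_that("vonmises_fit matches an exact-likelihood grid-search oracle", {
  set.seed(12)
  th <- rvonmises(1e4, mu = 0, kappa = 2)
  f <- vonmises_fit(th, fix_mu = 0)
  oracle <- vm_grid_oracle(th, 0)
  expect_equal(f$kappa, oracle, tolerance = 0.01)
  expect_equal(f$kappa, 2, tolerance = 0.05 * 2)
})

test_that("vonmises_fit is rotation-equivariant and monotone in resultant length", {
  set.seed(13)
  th <- rvonmises(2000, mu = 0.4, kappa = 3)
  f1 <- vonmises_fit(th)
  for (phi in c(-2, 0.5, 1.7)) {
    f2 <- vonmises_fit((th + phi + pi) %% (2 * pi) - pi)
    dmu <- (f2$mu - f1$mu - phi + pi) %% (2 * pi) - pi
    expect_lt(abs(dmu), 1e-6)
    expect_equal(f2$kappa, f1$kappa, tolerance = 1e-6)
  }
  # kappa increases with mean resultant length at fixed n
  rbars <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  kaps <- vapply(rbars, function(rb) {
    # synthetic two-point sample with prescribed resultant length
    a <- acos(rb)
    vonmises_fit(rep(c(-a, a), 50))$kappa
  }, numeric(1))
  expect_true(all(diff(kaps) > 0))
})

test_that("fixed-mean kappa recovery within 10% across kappa in {0.5,1,2,5}", {
  set.seed(14)
  fails <- 0L; total <- 0L
  for (k in c(0.5, 1, 2, 5)) {
    for (rep in 1:25) {
      th <- rvonmises(1e4, 0, k)
      est <- vonmises_fit(th, fix_mu = 0)$kappa
      total <- total + 1L
      if (abs(est - k) > 0.1 * k) fails <- fails + 1L
    }
  }
  expect_lte(fails / total, 0.05)
})

test_that("spontaneous_motility: exact on constructed tracks, recovery end-to-end", {
  d <- data.frame(track_id = rep(1:3, each = 4), t_min = rep(0:3, 3),
                  x_um = as.vector(sapply(c(0, 50, 100), function(o) o + 3.9 * (0:3))),
                  y_um = 0)
  class(d) <- c("track_set", "data.frame")
  expect_equal(spontaneous_motility(d), 3.9)
  still <- d; still$x_um <- 5
  expect_equal(spontaneous_motility(still), 0)

  p <- colony_preset("uniform-motility", seed = 2, n_cells = 150,
                     image_size = 512, duration = 0.25)
  times <- seq(0, 15, by = 1 / 3)
  sim <- simulate_colony(p, times)
  tp <- track_pipeline(sim, 0, 15, 3)
  expect_equal(spontaneous_motility(tp$tracks), 3.9, tolerance = 0.39)
})

test_that("step headings relative to the radial direction feed fixed-mean fits", {
  p <- tiny_kinematic(seed = 9, duration = 2)
  times <- sort(unique(c(0, 90 + seq(0, 10, by = 1))))
  sim <- simulate_colony(p, times)
  tracks <- tracks_from_agents(sim, 90, 100)
  vs <- velocity_samples(tracks, c(0, 0), 1, 0.5)
  coh <- unique(sim$agents$id[sim$agents$state == "corona"])
  ang <- step_headings(vs[vs$track_id %in% coh, ])
  expect_gt(length(ang), 200)
  fit <- vonmises_fit(ang, fix_mu = 0)
  expect_equal(fit$kappa, 0.5, tolerance = 0.2)
  free <- vonmises_fit(ang)
  expect_lt(abs(free$mu), 0.25)   # mean direction is radially outward
})
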