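# Corona detection, formation time, speeds, ring geometry and the
# area-conservation width model; expansion velocity; duplication ratio.

test_that("detect_corona: monotone profiles yield absence, constructed annuli are found", {
  decreasing <- profile_from_values(seq(80, 2, length.out = 40))
  expect_true(is.na(detect_corona(decreasing)))

  vals <- rep(0, 40); vals[18:20] <- 100        # annulus at [510, 600) um
  pr <- profile_from_values(vals)
  R <- detect_corona(pr)
  expect_true(R >= 500 && R < 600)

  expect_error(detect_corona(profile_from_values(c(1, 2, 3))), "5 radial bins")
})

test_that("formation_time: immediate, delayed, flickering and absent traces", {
  mk <- function(present) {
    structure(data.frame(t_min = seq_along(present) - 1,
                         R_um = ifelse(present, 500, NA), present = present),
              class = c("corona_trace", "data.frame"))
  }
  expect_equal(as.numeric(formation_time(mk(rep(TRUE, 10)))), 0)
  expect_true(is.na(formation_time(mk(rep(FALSE, 10)))))
  # single-frame flicker is suppressed; persistence starts the clock at the
  # first frame of the persistent run
  flick <- c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  ts <- formation_time(mk(flick), persistence = 3)
  expect_equal(as.numeric(ts), 4)
  expect_equal(attr(ts, "latency_bound"), 3)
})

test_that("initial_speed and late_speed are exact on noiseless piecewise-linear traces", {
  t <- seq(0, 1440, by = 5)
  R <- 950 + 2.2 * pmin(t, 600) + 0.67 * pmax(t - 600, 0)
  tr <- structure(data.frame(t_min = t, R_um = R, present = TRUE),
                  class = c("corona_trace", "data.frame"))
  expect_equal(initial_speed(tr, t_star = 0, window = 140), 2.2)
  expect_equal(as.numeric(late_speed(tr, 600, 1440)), 0.67, tolerance = 1e-12)

  flat <- tr; flat$R_um <- 1000
  expect_equal(initial_speed(flat, t_star = 0), 0)
  expect_equal(as.numeric(late_speed(flat)), 0)
  expect_error(initial_speed(tr[1, ], t_star = 0), "fewer than 2")
  expect_error(late_speed(tr[1:3, ]), "fewer than 5")
})

test_that("late_speed recovers a noisy slope within OLS theory", {
  set.seed(21)
  t <- seq(600, 1440, by = 6)
  miss <- 0
  for (rep in 1:20) {
    R <- 1500 + 0.67 * (t - 600) + rnorm(length(t), 0, 25)
    tr <- structure(data.frame(t_min = t, R_um = R, present = TRUE),
                    class = c("corona_trace", "data.frame"))
    vf <- late_speed(tr, 600, 1440)
    se <- attr(vf, "residual_sd") / (stats::sd(t) * sqrt(length(t) - 1))
    if (abs(as.numeric(vf) - 0.67) > 2 * se) miss <- miss + 1
  }
  expect_lte(miss, 3)   # ~5% expected outside 2 SE
})

test_that("ring_geometry: rectangular profiles, floors and binning", {
  vals <- rep(0, 60); vals[30:33] <- 80          # 120-um-wide rectangle
  profs <- lapply(seq(0, 54, by = 6), function(tt)
    profile_from_values(vals, time = tt))
  tr <- structure(data.frame(t_min = seq(0, 54, by = 6), R_um = 29.5 * 30,
                             present = TRUE),
                  class = c("corona_trace", "data.frame"))
  rg <- ring_geometry(profs, tr, density_floor = 40, smooth_width = 1)
  expect_true(all(rg$per_frame$width_um == 120))
  expect_true(all(abs(rg$per_frame$density_pct - 80) < 1e-9))
  expect_false(any(rg$per_frame$flagged))
  # floor above the peak: zero width, flagged
  rg2 <- ring_geometry(profs, tr, density_floor = 90, smooth_width = 1)
  expect_true(all(rg2$per_frame$width_um == 0))
  expect_true(all(rg2$per_frame$flagged))
  # binning a constant series: means equal the constant, sd 0
  expect_true(all(abs(rg$binned$width_um - 120) < 1e-9))
  expect_true(all(rg$binned$width_sd == 0))
})

test_that("ring_width_model conserves R*L and composes", {
  m <- ring_width_model(L0 = 200, R0 = 1000, R_t = c(1000, 1500, 2000))
  expect_equal(m$width_um, c(200, 200 * 1000 / 1500, 100))
  expect_true(all(abs(m$RL_um2 / (200 * 1000) - 1) < 1e-9))
  # R constant -> L constant; R doubles -> L halves
  expect_equal(ring_width_model(150, 800, 800)$width_um, 150)
  expect_equal(ring_width_model(150, 800, 1600)$width_um, 75)
  # composition: t -> t+d -> t+2d equals direct t -> t+2d
  L1 <- ring_width_model(150, 800, 1200)$width_um
  L2 <- ring_width_model(L1, 1200, 1600)$width_um
  expect_equal(L2, ring_width_model(150, 800, 1600)$width_um, tolerance = 1e-12)
  expect_error(ring_width_model(0, 800, 900), "positive")
  expect_error(ring_width_model(10, 800, c(900, -1)), "positive")
})

test_that("expansion_velocity: exact on translating profiles, zero on static ones, threshold-independent", {
  border_profiles <- function(speed) {
    # translating linear ramp: every threshold crossing moves at `speed`
    lapply(0:60, function(tt) {
      r <- (seq_len(60) - 0.5) * 30
      profile_from_values(pmax(0, pmin(50, (500 + speed * tt - r) / 5)),
                          time = tt)
    })
  }
  ev <- expansion_velocity(border_profiles(0.8), thresholds = c(10, 20, 30),
                           smooth_width = 1)
  expect_equal(ev$per_threshold$v_um_min, rep(0.8, 3), tolerance = 1e-9)
  expect_equal(ev$v_NC, 0.8, tolerance = 1e-9)
  # threshold independence on a translating fixed shape
  expect_lt(stats::sd(ev$per_threshold$v_um_min), 0.05 * ev$v_NC + 1e-12)

  ev0 <- expansion_velocity(border_profiles(0), thresholds = c(10, 20, 30),
                            smooth_width = 1)
  expect_equal(ev0$v_NC, 0)
  # unattained thresholds are dropped with a warning
  expect_warning(
    ev2 <- expansion_velocity(border_profiles(0.5), thresholds = c(10, 99),
                              smooth_width = 1),
    "dropped")
  expect_equal(nrow(ev2$per_threshold), 1)
})

test_that("duplication_estimate: conserved counts, exponential growth, empty sector", {
  # division off: sector ratio stays at 1 within sampling noise
  p0 <- colony_params(mode = "unconfined", n_cells = 2000, duration = 2,
                      seed = 13, base_speed = 3.9)
  s0 <- simulate_colony(p0, frame_times = seq(0, 120, by = 30))
  det0 <- lapply(seq(0, 120, by = 30), function(tt)
    agents_at(s0, tt)[, c("x_um", "y_um")])
  d0 <- duplication_estimate(det0, seq(0, 120, by = 30),
                             sector = list(theta = c(-pi, pi), r = c(0, 900)),
                             reference_time = 0)
  expect_equal(d0$ratio[1], 1)
  expect_true(all(abs(d0$ratio - 1) < 0.1))

  # division at rate g: ratio ~ exp(g t) within 10% at g*t <= 0.5
  pg <- colony_params(mode = "unconfined", n_cells = 2000, duration = 2,
                      seed = 14, base_speed = 3.9, division_rate = 0.25)
  sg <- simulate_colony(pg, frame_times = seq(0, 120, by = 30))
  detg <- lapply(seq(0, 120, by = 30), function(tt)
    agents_at(sg, tt)[, c("x_um", "y_um")])
  dg <- duplication_estimate(detg, seq(0, 120, by = 30),
                             sector = list(theta = c(0, pi), r = c(0, 2000)),
                             reference_time = 0)
  g <- 0.25 / 60
  expect_equal(dg$ratio, exp(g * dg$t_min), tolerance = 0.1)

  expect_error(
    duplication_estimate(det0, seq(0, 120, by = 30),
                         sector = list(theta = c(0, 0.1), r = c(5000, 6000)),
                         reference_time = 0),
    "no detections")
})

test_that("full kinematic pipeline recovers formation time and initial speed from images", {
  p <- colony_preset("AX2-confined", seed = 1, duration = 6)
  sim <- simulate_colony(p, frame_times = seq(0, 360, by = 5))
  trace <- corona_trace(profile_series(sim))
  kin <- corona_kinetics(trace, vi_window = 140, vf_from = 240, vf_to = 360)
  # T* within formation (60) + persistence latency + ring-separation carving
  # time (half cohort width / initial speed)
  expect_true(is.finite(kin$T_star))
  expect_gte(kin$T_star, 60)
  expect_lte(kin$T_star, 60 + attr(formation_time(trace), "latency_bound") +
               p$ring_width_initial / 2 / p$ring_speed_initial + 10)
  expect_equal(kin$v_i, 2.2, tolerance = 0.1)
  # before the crossover the "late" OLS window sees the same initial speed
  expect_equal(kin$v_f, 2.2, tolerance = 0.1)
  # displacement is zero at T* by construction
  expect_equal(kin$displacement$dR_um[kin$displacement$t_min == kin$T_star], 0)
})
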