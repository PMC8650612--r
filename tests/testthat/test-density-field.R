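# Binarization, brightness fractions, centring, radial profiles, spot
# detection and grid counts.

test_that("binarize_adaptive: parameter checks, constant frames, polarity", {
  fr <- matrix(50, 64, 64)
  expect_error(binarize_adaptive(fr, block_size = 50), "odd")
  expect_error(binarize_adaptive(fr, block_size = 1), "odd")
  # strict inequality: a constant image is all background for offset <= 0
  expect_false(any(binarize_adaptive(fr, offset = 0)$mask))
  expect_false(any(binarize_adaptive(fr)$mask))
  # dark polarity: dark blob on bright background
  fr2 <- matrix(200, 64, 64); fr2[30:34, 30:34] <- 20
  bf <- binarize_adaptive(fr2, block_size = 31, offset = -20, polarity = "dark")
  expect_true(all(bf$mask[30:34, 30:34]))
  expect_false(any(bf$mask[1:10, 1:10]))
})

test_that("binarize_adaptive matches a global Otsu oracle on a two-level image", {
  skip_if_not_installed("EBImage")
  fr <- matrix(10, 128, 128)
  fr[60:71, 40:51] <- 110
  bf <- binarize_adaptive(fr, block_size = 51, offset = -20)
  th <- EBImage::otsu(EBImage::Image(fr / 255), range = c(0, 1)) * 255
  oracle <- fr > th
  jacc <- sum(bf$mask & oracle) / sum(bf$mask | oracle)
  expect_gte(jacc, 0.9)
})

test_that("foreground fraction of sparse rendered agents matches the footprint estimate", {
  p <- colony_params(mode = "uniform", n_cells = 200, pixel_size = 2,
                     image_size = 512, noise_sd = 0, seed = 9, duration = 0.1)
  pts <- place_separated(200, half = 460, min_sep = 25, seed = 9)
  fr <- render_frame(pts, p)
  bf <- binarize_adaptive(fr, pixel_size = 2)
  frac <- brightness_fraction(bf)
  expected <- 200 * pi * p$cell_render_radius^2 / (1024^2)
  expect_gt(frac, 0.8 * expected)
  expect_lt(frac, 1.2 * expected)
})

test_that("brightness_fraction: exact values and monotonicity under foreground addition", {
  m <- matrix(FALSE, 40, 40)
  expect_equal(brightness_fraction(bf_from_mask(m)), 0)
  expect_equal(brightness_fraction(bf_from_mask(!m)), 1)
  half <- m; half[, 1:20] <- TRUE
  expect_equal(brightness_fraction(bf_from_mask(half)), 0.5)
  # region variants
  bf <- bf_from_mask(half, pixel_size = 2)
  expect_equal(brightness_fraction(bf, region_rect(c(-40, 0), c(-40, 40))), 1)
  expect_error(brightness_fraction(bf, region_disc(c(500, 500), 5)),
               "intersect")
  # monotone: adding white pixels never decreases the fraction
  set.seed(1)
  cur <- m
  prev_frac <- 0
  for (k in 1:20) {
    cur[sample(length(cur), 30)] <- TRUE
    f <- brightness_fraction(bf_from_mask(cur))
    expect_gte(f, prev_frac)
    prev_frac <- f
  }
})

test_that("estimate_center: symmetric masks and synthetic colony frames", {
  n <- 101
  xs <- matrix(rep(1:n, each = n), n); ys <- t(xs)
  disc <- (xs - 51)^2 + (ys - 51)^2 < 20^2
  ctr <- estimate_center(bf_from_mask(disc, pixel_size = 2))
  expect_lt(max(abs(ctr)), 2)     # within 1 px of the frame centre
  two <- (xs - 31)^2 + (ys - 51)^2 < 10^2 | (xs - 71)^2 + (ys - 51)^2 < 10^2
  expect_lt(max(abs(estimate_center(bf_from_mask(two, pixel_size = 2)))), 1e-9)
  expect_error(estimate_center(bf_from_mask(matrix(FALSE, 5, 5))), "empty")

  p <- tiny_kinematic(seed = 6, n_cells = 2000)
  sim <- simulate_colony(p, frame_times = 0)
  fr <- render_frames(sim)$frames[[1]]
  bf <- binarize_adaptive(fr, pixel_size = p$pixel_size)
  expect_lt(sqrt(sum(estimate_center(bf)^2)), 20)
})

test_that("radial_profile: flat masks, constructed annuli, rotation invariance", {
  n <- 200; ps <- 2
  full <- bf_from_mask(matrix(TRUE, n, n), pixel_size = ps)
  pr <- radial_profile(full, c(0, 0), bin_width = 30)
  expect_true(all(abs(pr$relative_density - 100) < 1e-9))

  xs <- matrix(rep(1:n, each = n), n); ys <- t(xs)
  xu <- (xs - 0.5) * ps - n * ps / 2
  yu <- (ys - 0.5) * ps - n * ps / 2
  r_um <- sqrt(xu^2 + yu^2)
  ann <- r_um >= 90 & r_um < 150
  pr2 <- radial_profile(bf_from_mask(ann, pixel_size = ps), c(0, 0), 30)
  covered <- pr2$bin_center_um > 90 & pr2$bin_center_um < 150
  expect_true(all(pr2$relative_density[covered] > 99))
  expect_true(all(pr2$relative_density[pr2$bin_center_um < 90 |
                                         pr2$bin_center_um > 150] < 1e-9))

  # rotation invariance (90 degrees about the frame centre is exact)
  set.seed(4)
  blob <- r_um < 120 & matrix(runif(n * n), n) < 0.4
  rot <- t(blob)[, n:1]
  prA <- radial_profile(bf_from_mask(blob, pixel_size = ps), c(0, 0), 30)
  prB <- radial_profile(bf_from_mask(rot, pixel_size = ps), c(0, 0), 30)
  expect_equal(prA$relative_density, prB$relative_density, tolerance = 0.01)
})

test_that("profile argmax tracks the ground-truth ring in a kinematic run", {
  p <- tiny_kinematic(seed = 3, duration = 3)
  sim <- simulate_colony(p, frame_times = seq(60, 180, by = 15))
  profs <- profile_series(sim)
  hits <- 0L; tot <- 0L
  for (pr in profs) {
    tt <- attr(pr, "t_min")
    R_true <- ring_radius_kinematic(p, tt)
    det <- detect_corona(pr)
    tot <- tot + 1L
    if (is.finite(det) && abs(det - R_true) <= 60) hits <- hits + 1L
  }
  expect_gte(hits / tot, 0.9)
})

test_that("count_cells_grid: empty frames, exact counts, conservation, tiling", {
  p <- colony_params(mode = "uniform", n_cells = 50, pixel_size = 2,
                     image_size = 256, noise_sd = 0, seed = 1, duration = 0.1)
  empty <- render_frame(data.frame(x_um = numeric(0), y_um = numeric(0)), p)
  g0 <- count_cells_grid(empty, tile = 100, pixel_size = 2)
  expect_equal(nrow(g0$detections), 0)
  expect_equal(sum(g0$counts$count), 0)

  # noise-free non-overlapping agents are counted exactly, 100 seeds
  exact <- 0L
  for (s in 1:100) {
    pts <- place_separated(50, half = 230, min_sep = 18, seed = s)
    fr <- render_frame(pts, p)
    g <- count_cells_grid(fr, tile = 100, pixel_size = 2)
    if (nrow(g$detections) == 50) exact <- exact + 1L
    expect_equal(sum(g$counts$count), nrow(g$detections))  # conservation
  }
  expect_equal(exact, 100L)

  # half-open tiling: a detection on a boundary sits in exactly one tile
  pts <- data.frame(x_um = 0, y_um = 0)   # exactly on the tile boundary
  fr <- render_frame(pts, p)
  g <- count_cells_grid(fr, tile = 100, pixel_size = 2)
  expect_equal(sum(g$counts$count), nrow(g$detections))
  expect_equal(nrow(g$counts), nrow(g$detections))
})
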