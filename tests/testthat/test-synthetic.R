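test_that("cone generator obeys trivial limits and is seed-deterministic", {
  # zero amplitude: every vector equals the axis
  os <- gen_cone_orientations(cone_spec(0, tau = 10, n_frames = 50, seed = 1))
  expect_equal(os$vectors, matrix(rep(c(0, 0, 1), 50), ncol = 3, byrow = TRUE))
  expect_equal(as.numeric(order_parameter_total(os)), 1)

  a <- gen_cone_orientations(cone_spec(30, 20, 1, 500, seed = 7))
  b <- gen_cone_orientations(cone_spec(30, 20, 1, 500, seed = 7))
  c <- gen_cone_orientations(cone_spec(30, 20, 1, 500, seed = 8))
  expect_identical(a$vectors, b$vectors)
  expect_false(identical(a$vectors, c$vectors))

  expect_error(cone_spec(-1, 10, 1, 100), "semi_angle")
  expect_error(cone_spec(30, -5, 1, 100), "tau")
  expect_error(cone_spec(30, 10, 1, 1), "n_frames")
})

test_that("cone equilibrium density is uniform over solid angle in the cone", {
  # small-step regime (tau >> dt), where the reflecting boundary does not
  # distort the stationary density; draws are decorrelated by subsampling
  theta_c <- 50
  tau <- 50
  os <- gen_cone_orientations(cone_spec(theta_c, tau, 1, 2e5, seed = 13))
  keep <- seq(1, length(os), by = 5 * tau)
  cth <- os$vectors[keep, 3]
  c0 <- cos(theta_c * pi / 180)
  ks <- suppressWarnings(stats::ks.test((cth - c0) / (1 - c0), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("long cone series converge to the closed-form order parameter", {
  os90 <- gen_cone_orientations(cone_spec(90, 5, 1, 2e5, seed = 3))
  expect_lt(abs(as.numeric(order_parameter_total(os90))), 0.05)

  os47 <- gen_cone_orientations(cone_spec(47.2, 5, 1, 2e5, seed = 4))
  expect_equal(as.numeric(order_parameter_total(os47)),
               cone_order_parameter(47.2), tolerance = 0.02)
  expect_equal(cone_order_parameter(47.2), 0.57, tolerance = 0.01)
})

test_that("composite generator honors its ground-truth product rule", {
  n <- 2e5
  fast0 <- composite_spec(cone_spec(0, 0.5, 1, n), cone_spec(40, 100, 1, n),
                          seed = 5)
  gt <- attr(gen_composite_orientations(fast0), "ground_truth")
  expect_equal(gt$S_fast, 1)
  expect_equal(gt$S_total, gt$S_slow)

  # fast semi-angle zero reduces to a pure slow cone
  S0 <- as.numeric(order_parameter_total(gen_composite_orientations(fast0)))
  expect_equal(S0, cone_order_parameter(40), tolerance = 0.02)

  slow0 <- composite_spec(cone_spec(30, 0.5, 1, n), cone_spec(1e-9, 100, 1, n),
                          seed = 5)
  # a (vanishingly small) slow cone: S_total is set by the fast motion alone
  Sf <- as.numeric(order_parameter_total(gen_composite_orientations(slow0)))
  expect_equal(Sf, cone_order_parameter(30), tolerance = 0.02)

  # product rule at S_fast = 0.9, S_slow = 0.8
  th_f <- cone_semi_angle(0.9)
  th_s <- cone_semi_angle(0.8)
  cs <- composite_spec(cone_spec(th_f, 0.5, 1, n), cone_spec(th_s, 100, 1, n),
                       seed = 11)
  co <- gen_composite_orientations(cs)
  expect_equal(attr(co, "ground_truth")$S_total, 0.72)
  S <- as.numeric(order_parameter_total(co))
  expect_equal(S, 0.72, tolerance = 0.02)
  expect_error(composite_spec(cone_spec(10, 100, 1, n), cone_spec(20, 5, 1, n)),
               "tau")
})

test_that("helix fixture reproduces ideal helix geometry and driving axis", {
  geom <- helix_geometry(4)
  tr <- gen_helix_trajectory(geom, orientation_series(matrix(c(0, 0, 1), 1)))
  ca <- tr$xyz[1, tr$atoms$name == "CA", ]
  # closed-form adjacent C-alpha spacing of the ideal helix
  d_expected <- sqrt(geom$rise_per_residue^2 +
                       (2 * geom$radius * sin(pi * geom$twist_per_residue / 360))^2)
  d_obs <- sqrt(rowSums(diff(ca)^2))
  expect_equal(d_obs, rep(d_expected, 3), tolerance = 1e-10)

  # static axis: the cylinder fit returns it exactly
  tr10 <- gen_helix_trajectory(helix_geometry(10),
                               orientation_series(matrix(c(0, 0, 1), 1)))
  f <- fit_cylinder_axis(tr10$xyz[1, tr10$atoms$name == "CA", ])
  expect_equal(abs(f$axis[3]), 1, tolerance = 1e-6)

  # driven by a cone series: fitted axes reproduce the series' order parameter
  drv <- gen_cone_orientations(cone_spec(35, 10, 1, 400, seed = 21))
  trj <- gen_helix_trajectory(helix_geometry(12), drv)
  ser <- segment_orientation_series(
    trj, list(name = "H", sub_segment = "x", first = 1, last = 12,
              topo_class = "helix_extracellular"))
  expect_equal(as.numeric(order_parameter_total(ser)),
               as.numeric(order_parameter_total(drv)), tolerance = 1e-3)

  expect_error(helix_geometry(10, radius = -1), "radius")
})

test_that("synthetic CP and dephasing curves obey their limiting behaviour", {
  iso <- list(I0 = 1, T_IS = 1000 / 3, T1rho = 4000)
  cp <- gen_cp_curve(c(0, 1e5), iso, iso, noise_sd = 0)
  expect_equal(cp$iso_area[1], 0)
  expect_lt(abs(cp$iso_area[2]), 1e-8)

  # curve maximum near the closed-form optimum contact time (0.90 ms)
  tt <- seq(1, 4000, by = 1)
  y <- is_model_intensity(tt, 1, 1000 / 3, 4000)
  expect_equal(tt[which.max(y)], 904, tolerance = 0.01)

  flat <- gen_dephasing_curve(0, 5)
  expect_true(all(flat$intensity == 1))
  cur <- gen_dephasing_curve(21.5, 5, noise_sd = 0)
  expect_equal(cur$intensity[1], 1, tolerance = 1e-9)
  expect_equal(cur$intensity[length(cur$intensity)], 1, tolerance = 1e-3)
})

test_that("orientation series TSV round trip preserves data", {
  os <- gen_cone_orientations(cone_spec(25, 10, 0.5, 100, seed = 2))
  p <- tempfile(fileext = ".tsv")
  write_orientation_series(os, p, metadata = list(seed = 2))
  back <- read_orientation_series(p)
  expect_equal(back$vectors, os$vectors, tolerance = 1e-9)
  expect_equal(back$dt, os$dt)
  unlink(p)
})
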