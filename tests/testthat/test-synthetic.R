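test_that("noiseless area series follow the closed-form slope exactly", {
  g <- default_geom; p <- default_props; d <- experiment_design()
  ser <- gen_area_series(1, d, g, p, noise_frac = 0, seed = 1)
  slopes <- diff(ser$area_um2) / diff(ser$time_min)
  expect_equal(slopes, rep(surface_shrink_rate(p, g) / g$c_SA,
                           length(slopes)), tolerance = 1e-9)
  flat <- gen_area_series(1, d, g, medium_properties(saturation = 1),
                          noise_frac = 0, seed = 1)
  expect_equal(diff(range(flat$area_um2)), 0)
})

test_that("generators are pure functions of parameters and seed", {
  d <- experiment_design()
  a1 <- gen_area_series(0.5, d, default_geom, default_props, seed = 9)
  a2 <- gen_area_series(0.5, d, default_geom, default_props, seed = 9)
  expect_identical(a1, a2)
  t1 <- gen_tracks(10, 5, d, default_geom, default_props, seed = 9)
  t2 <- gen_tracks(10, 5, d, default_geom, default_props, seed = 9)
  expect_identical(t1, t2)
  f1 <- gen_frames(t1$tracks[1:2], seed = 9)
  f2 <- gen_frames(t2$tracks[1:2], seed = 9)
  expect_identical(f1, f2)
  s1 <- gen_survival_panel(d, default_geom, default_props, seed = 9)
  s2 <- gen_survival_panel(d, default_geom, default_props, seed = 9)
  expect_identical(s1, s2)
  # a different seed perturbs the noise
  a3 <- gen_area_series(0.5, d, default_geom, default_props, seed = 10)
  expect_false(identical(a1$area_um2, a3$area_um2))
})

test_that("noiseless FP pairs invert back to the generating viscosities", {
  eta <- c(0.9, 1.876, 3.2, 8)
  fp <- gen_fp_series(eta, noise_frac = 0, seed = 1)
  p <- polarization(fp$I_par, fp$I_perp)
  expect_equal(perrin_viscosity(p), eta, tolerance = 1e-9)
  expect_true(all(diff(p) > 0))   # increasing viscosity, increasing p
})

test_that("generated track speeds reflect viscosity scaling when stress is off", {
  d <- experiment_design()
  tk <- gen_tracks(60, 1000, d, default_geom, default_props, gamma = 0,
                   seed = 4)
  ep_eta <- tk$eta_30
  v_expected <- 66 * default_props$eta_s0 / ep_eta
  expect_equal(tk$v_expected, v_expected, tolerance = 1e-12)
  measured <- mean(tk$speeds[tk$motile])
  expect_equal(measured, v_expected, tolerance = 0.04)
})

test_that("the configured immotile fraction shows up in raw motility", {
  d <- experiment_design(immotile_frac = 0.3)
  tk <- gen_tracks(50, 100, d, default_geom, default_props, seed = 6)
  expect_equal(mean(!tk$motile), 0.3, tolerance = 0.02)
  raw <- motility_percent(tk$tracks, threshold = 5)
  expect_equal(raw, 70, tolerance = 0.1)
})

test_that("survival panels carry the designed volume structure", {
  d <- experiment_design()
  panel <- gen_survival_panel(d, default_geom, default_props, seed = 1)
  expect_equal(nrow(panel), length(d$volumes_nL) * d$replicates)
  expect_true(all(panel$motility_postthaw_pct[panel$V0_nL < 30] == 0))
  expect_true(all(panel$motility_postthaw_pct[panel$V0_nL >= 30] > 0))
  # ~40% velocity drop at 1 nL relative to the >= 10 nL plateau
  small <- mean(panel$velocity_um_s[panel$V0_nL == 1])
  plateau <- mean(panel$velocity_um_s[panel$V0_nL >= 10])
  expect_gt(small / plateau, 0.55)
  expect_lt(small / plateau, 0.65)
  # motility at 30 min only mildly reduced in the mid-range
  expect_gt(mean(panel$motility_30min_pct[panel$V0_nL >= 10]), 85)
})

test_that("rendered frames clip out-of-field spots and keep ground truth", {
  inside <- data.frame(time_s = 0, x_um = 30, y_um = 30)
  outside <- data.frame(time_s = 0, x_um = 500, y_um = 30)
  fr <- gen_frames(list(inside, outside), image_size = c(64, 64),
                   snr = Inf, seed = 1)
  expect_equal(attr(fr, "n_clipped"), 1)
  expect_equal(nrow(attr(fr, "positions")[[1]]), 1)
  none <- gen_frames(list(), image_size = c(16, 16), snr = Inf, seed = 1)
  expect_true(all(none[[1]] == 0))   # no cells: blank frame
})

test_that("stress factor is inactive at gamma 0 and caps at 1", {
  expect_equal(stress_factor(c(1, 2, 10), gamma = 0), c(1, 1, 1))
  expect_equal(stress_factor(2, gamma = 4), 2^-4)
  expect_equal(stress_factor(0.5, gamma = 4), 1)   # dilution never boosts
})
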