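test_that("the two shrink-rate routes give ~-108 um^2/min and agree within 1.5%", {
  g <- default_geom; p <- default_props
  r_diff <- surface_shrink_rate(p, g)
  r_meas <- shrink_rate_from_dAdt(-88.4, g)
  expect_equal(r_meas, -108.5, tolerance = 0.001)
  expect_equal(r_diff, -108.35, tolerance = 0.01)
  expect_lt(abs(r_diff / r_meas - 1), 0.015)
})

test_that("saturated oil or zero DC0 freezes the shrinkage entirely", {
  g <- default_geom
  expect_equal(surface_shrink_rate(medium_properties(saturation = 1), g), 0)
  expect_equal(surface_shrink_rate(medium_properties(DC0 = 0), g), 0)
  expect_equal(shrink_rate_from_dAdt(0, g), 0)
  expect_equal(boundary_flux(123, medium_properties(saturation = 1), g), 0)
  tr <- simulate_shrinkage(0.5, 30, 1, g, medium_properties(saturation = 1))
  expect_equal(tr$V_nL, rep(0.5, nrow(tr)), tolerance = 1e-12)
  expect_equal(tr$eta_cP, rep(tr$eta_cP[1], nrow(tr)), tolerance = 1e-12)
})

test_that("interfacial flux follows the S^(-1/2) law with the right magnitude", {
  g <- default_geom; p <- default_props
  # independent arithmetic: sqrt(2.3290487) * 1.88e-10 / sqrt(1e-8 m^2)
  expect_equal(boundary_flux(1e4, p, g),
               sqrt(g$c_S) * 1.88e-10 / 1e-4, tolerance = 1e-12)
  expect_equal(boundary_flux(1e4, p, g), 2.87e-6, tolerance = 0.005)
  expect_equal(boundary_flux(4e4, p, g), boundary_flux(1e4, p, g) / 2,
               tolerance = 1e-12)
  expect_error(boundary_flux(0, p, g), "positive")
})

test_that("shrinkage trajectories conserve solute and are linear in S", {
  g <- default_geom; p <- default_props
  for (V0 in c(0.1, 1, 50)) {
    tr <- simulate_shrinkage(V0, 30, 0.5, g, p)
    n0 <- attr(tr, "n0")
    expect_equal(tr$C_mol_m3 * tr$V_um3 * 1e-18, rep(n0, nrow(tr)),
                 tolerance = 1e-9)
    # S(t) exactly linear
    fit <- diff(tr$S_um2) / diff(tr$time_min)
    expect_equal(max(fit) - min(fit), 0, tolerance = 1e-8)
    expect_true(all(diff(tr$S_um2) < 0))
    expect_true(all(tr$V_um3 > 0))
  }
})

test_that("a 0.1-nL droplet loses 45-47% of its volume in 30 minutes", {
  tr <- simulate_shrinkage(0.1, 30, 1, default_geom, default_props)
  loss <- 1 - tr$V_nL[nrow(tr)] / 0.1
  expect_gt(loss, 0.45)
  expect_lt(loss, 0.47)
  expect_true(is.na(attr(tr, "vanished_at")))
})

test_that("droplets that evaporate fully are truncated and time-stamped", {
  g <- default_geom; p <- default_props
  # vanishing volume: surface lost in 30 min ~ 3244 um^2
  V_small <- um3_to_nl(volume_from_surface(
    abs(surface_shrink_rate(p, g)) * 10, g))   # vanishes at t = 10 min
  tr <- simulate_shrinkage(V_small, 30, 1, g, p)
  expect_equal(attr(tr, "vanished_at"), 10, tolerance = 1e-9)
  expect_lt(max(tr$time_min), 10)
})

test_that("concentration rate follows the fixed-solute V^(-5/3) law", {
  g <- default_geom; p <- default_props
  V <- c(0.1, 0.5, 1, 3, 10, 100)
  r1 <- concentration_rate(V, g, p, n0 = 1e-9)
  r2 <- concentration_rate(2 * V, g, p, n0 = 1e-9)
  expect_equal(r1 / r2, rep(2^(5 / 3), length(V)), tolerance = 1e-12)
  expect_equal(concentration_rate(1, g, p, n0 = 1e-9) /
                 concentration_rate(100, g, p, n0 = 1e-9),
               100^(5 / 3), tolerance = 1e-9)
  expect_equal(concentration_rate(1, medium_properties(saturation = 1),
                                  geom = g, n0 = 1e-9), 0)
})

test_that("concentration rate matches a finite difference of the trajectory", {
  g <- default_geom; p <- default_props
  for (V0 in c(0.2, 2, 20)) {
    n0 <- solute_amount(V0, p)
    tr <- simulate_shrinkage(V0, duration = 0.02, dt = 0.01, geom = g,
                             props = p)
    fd <- (tr$C_mol_m3[2] - tr$C_mol_m3[1]) / 0.01
    expect_equal(concentration_rate(V0, g, p, n0 = n0), fd,
                 tolerance = 1e-3)
  }
})

test_that("the dC/dS prefactor reproduces -1.4e-8 at the quoted solute amount", {
  g <- default_geom
  expect_equal(dCdt_prefactor(1e-9, g), -1.4e-8, tolerance = 0.02)
  expect_equal(dCdt_prefactor(2e-9, g), 2 * dCdt_prefactor(1e-9, g))
  # physiological solute content of a 1-nL droplet: 0.15 Osm * 1e-9 L
  n0 <- solute_amount(1, default_props)
  expect_equal(n0, 1.5e-10)
  expect_equal(dCdt_prefactor(n0, g), -2.1e-9, tolerance = 0.01)
  expect_error(dCdt_prefactor(0, g), "positive")
})

test_that("DC0 is recovered from area series and degenerate series are handled", {
  g <- default_geom; p <- default_props
  ser <- gen_area_series(0.1, experiment_design(), g, p, noise_frac = 0,
                         seed = 1)
  est <- suppressWarnings(estimate_DC0(ser, g, p))
  expect_equal(est$DC0, 1.88e-10, tolerance = 1e-3)
  flat <- data.frame(time_min = 0:10, area_um2 = rep(500, 11))
  expect_equal(suppressWarnings(estimate_DC0(flat, g, p))$DC0, 0)
  expect_error(estimate_DC0(ser[1:2, ], g, p), "at least 3")
  growing <- data.frame(time_min = 0:10, area_um2 = 500 + 10 * (0:10))
  expect_error(suppressWarnings(estimate_DC0(growing, g, p)), "cannot grow")
  shuffled <- ser[c(2, 1, 3:nrow(ser)), ]
  expect_error(estimate_DC0(shuffled, g, p), "strictly increasing")
})

test_that("critical volume matches the closed form and is monotone in the factor", {
  g <- default_geom; p <- default_props
  rate <- surface_shrink_rate(p, g)
  for (f in c(1.2, 2, 5)) {
    vc <- critical_volume(30, f, g, p)
    expect_equal(vc, oracle_critical_volume(30, f, rate, g$c_VS),
                 tolerance = 1e-6)
    tr <- simulate_shrinkage(vc, 30, 30, g, p)
    expect_equal(tr$C_mol_m3[nrow(tr)] / tr$C_mol_m3[1], f,
                 tolerance = 1e-6)
  }
  vs <- vapply(c(1.1, 1.5, 2, 4, 8), critical_volume, numeric(1),
               duration = 30, geom = g, props = p)
  expect_true(all(diff(vs) < 0))
  # a faster-shrinking system has a larger critical volume
  fast <- medium_properties(DC0 = 2 * p$DC0)
  expect_gt(critical_volume(30, 2, g, fast), critical_volume(30, 2, g, p))
  expect_error(critical_volume(30, 2, g, medium_properties(saturation = 1)),
               "no finite")
})
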