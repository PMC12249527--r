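test_that("coefficients at the measured 51-degree contact angle match their published roundings", {
  g <- cap_geometry(51)
  expect_equal(g$c_S, 2.329, tolerance = 0.005)
  expect_equal(g$c_V, 0.378, tolerance = 0.005)
  expect_equal(g$c_SA, 1.228, tolerance = 0.005)
  expect_equal(g$c_VS, 0.106, tolerance = 0.005)
  expect_equal(g$c_VA, 0.145, tolerance = 0.005)
})

test_that("hemisphere and near-sphere limits recover the closed forms", {
  h <- cap_geometry(90)
  expect_equal(h$c_S, 2 * pi)
  expect_equal(h$c_V, 2 * pi / 3)
  expect_equal(h$c_SA, 2)
  expect_equal(surface_from_radius(1, h), 2 * pi)
  expect_equal(volume_from_radius(1, h), 2 * pi / 3)
  # alpha -> 180: volume tends to the full sphere (4/3) pi R^3
  expect_equal(cap_geometry(180 - 1e-6)$c_V, 4 * pi / 3, tolerance = 1e-9)
})

test_that("the five coefficients satisfy their defining identities at any angle", {
  for (alpha in c(5, 23, 51, 90, 120, 151, 179)) {
    g <- cap_geometry(alpha)
    expect_equal(g$c_VS * g$c_S^1.5, g$c_V, tolerance = 1e-12)
    expect_equal(g$c_VA, g$c_VS * g$c_SA^1.5, tolerance = 1e-12)
    expect_true(all(unlist(g[c("c_S", "c_V", "c_SA", "c_VS", "c_VA")]) > 0))
  }
})

test_that("c_S and c_V increase strictly with contact angle", {
  alphas <- seq(1, 179, by = 2)
  cs <- vapply(alphas, function(a) cap_geometry(a)$c_S, numeric(1))
  cv <- vapply(alphas, function(a) cap_geometry(a)$c_V, numeric(1))
  expect_true(all(diff(cs) > 0))
  expect_true(all(diff(cv) > 0))
})

test_that("forward and inverse conversions are mutual inverses on positive inputs", {
  set.seed(7)
  for (alpha in c(30, 51, 90, 140)) {
    g <- cap_geometry(alpha)
    x <- 10^runif(25, -2, 6)   # log-uniform areas / volumes
    expect_equal(area_from_surface(surface_from_area(x, g), g), x,
                 tolerance = 1e-12)
    expect_equal(surface_from_volume(volume_from_surface(x, g), g), x,
                 tolerance = 1e-12)
    expect_equal(area_from_volume(volume_from_area(x, g), g), x,
                 tolerance = 1e-12)
    R <- 10^runif(25, -1, 3)
    expect_equal(radius_from_area(pi * (R * sin(alpha * pi / 180))^2, g), R,
                 tolerance = 1e-12)
  }
})

test_that("scaling laws hold: quadratic in R, 3/2-power in S", {
  g <- cap_geometry(51)
  expect_equal(surface_from_radius(2, g), 4 * surface_from_radius(1, g))
  expect_equal(volume_from_surface(400, g), 8 * volume_from_surface(100, g))
  expect_equal(surface_from_radius(10, g), 232.9, tolerance = 0.005)
  expect_equal(volume_from_radius(10, g), 378, tolerance = 0.005)
  expect_equal(surface_from_area(100, g), 122.8, tolerance = 0.005)
  expect_equal(volume_from_surface(100, g), 106, tolerance = 0.005)
  expect_equal(volume_from_area(100, g), 145, tolerance = 0.005)
})

test_that("the two routes from footprint area to volume agree exactly", {
  g <- cap_geometry(51)
  A <- 10^seq(-1, 5, length.out = 13)
  expect_equal(volume_from_area(A, g),
               volume_from_surface(surface_from_area(A, g), g),
               tolerance = 1e-12)
  # composed route agrees with volume_from_radius for any R
  R <- 10^seq(-1, 3, length.out = 9)
  expect_equal(volume_from_surface(surface_from_radius(R, g), g),
               volume_from_radius(R, g), tolerance = 1e-10)
})

test_that("a 30-nL droplet's footprint area inverts back to 30 nL", {
  g <- cap_geometry(51)
  A <- (30e6 / g$c_VA)^(2 / 3)
  expect_equal(um3_to_nl(volume_from_area(A, g)), 30, tolerance = 1e-12)
  expect_equal(radius_from_area(100, g), sqrt(100 / pi) / sin(51 * pi / 180),
               tolerance = 1e-12)
  expect_equal(radius_from_area(100, g), 7.26, tolerance = 1e-3)
})

test_that("degenerate angles and nonpositive inputs are rejected", {
  expect_error(cap_geometry(0), "between 0 and 180")
  expect_error(cap_geometry(180), "between 0 and 180")
  expect_error(cap_geometry(-10), "between 0 and 180")
  g <- cap_geometry(51)
  expect_error(surface_from_radius(0, g), "positive")
  expect_error(volume_from_surface(-1, g), "positive")
  expect_error(radius_from_area(0, g), "positive")
  expect_error(surface_from_area(5, "not a geometry"), "cap_geometry")
})
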