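test_that("a single smoothly moving detection yields one full-length track", {
  frames <- lapply(0:9, function(i) data.frame(x_um = 3 * i, y_um = 0))
  tracks <- link_detections(frames, dt = 1, max_disp = 10)
  expect_length(tracks, 1)
  expect_equal(nrow(tracks[[1]]), 10)
  expect_equal(track_velocity(tracks[[1]]), 3)
})

test_that("detections farther apart than the gate are never merged", {
  frames <- lapply(0:4, function(i)
    data.frame(x_um = c(0, 100) + 2 * i, y_um = c(0, 0)))
  tracks <- link_detections(frames, dt = 1, max_disp = 10)
  expect_length(tracks, 2)
  expect_true(all(vapply(tracks, nrow, integer(1)) == 5))
  # but a gate below the frame-to-frame step breaks every link
  broken <- link_detections(frames, dt = 1, max_disp = 1)
  expect_length(broken, 10)
})

test_that("the tracker recovers essentially all links on generated non-crossing tracks", {
  tk <- gen_tracks(25, 100, experiment_design(), default_geom,
                   default_props, seed = 3)
  linked <- link_detections(tk$frames, dt = 0.04, max_disp = 10)
  expect_length(linked, 25)
  expect_true(all(vapply(linked, nrow, integer(1)) == 25))
  # positions of each linked track coincide with one ground-truth track
  starts_linked <- sort(vapply(linked, function(tr) tr$x_um[1], numeric(1)))
  starts_truth <- sort(vapply(tk$tracks, function(tr) tr$x_um[1], numeric(1)))
  expect_equal(starts_linked, starts_truth)
})

test_that("curvilinear velocity matches closed forms", {
  straight <- data.frame(time_s = c(0, 1), x_um = c(0, 66), y_um = c(0, 0))
  expect_equal(track_velocity(straight), 66, tolerance = 1e-9)
  still <- data.frame(time_s = 0:5, x_um = rep(1, 6), y_um = rep(2, 6))
  expect_equal(track_velocity(still), 0)
  circ <- circular_track(r = 10, omega = 1, dt = 0.005, n = 400)
  expect_equal(track_velocity(circ), 10, tolerance = 1e-4)
  expect_error(track_velocity(straight[1, , drop = FALSE]), "at least 2")
})

test_that("motility classification uses an inclusive threshold", {
  fast <- data.frame(time_s = c(0, 1), x_um = c(0, 66), y_um = c(0, 0))
  slow <- data.frame(time_s = c(0, 1), x_um = c(0, 1), y_um = c(0, 0))
  at <- data.frame(time_s = c(0, 1), x_um = c(0, 5), y_um = c(0, 0))
  expect_true(classify_motile(fast, 5))
  expect_false(classify_motile(slow, 5))
  expect_true(classify_motile(at, 5))   # boundary counts as motile
})

test_that("percent motility normalizes to the initial value and is order-invariant", {
  mk <- function(v) data.frame(time_s = c(0, 1), x_um = c(0, v), y_um = 0)
  trajs <- c(lapply(rep(40, 4), mk), lapply(rep(1, 6), mk))
  expect_equal(motility_percent(trajs, 5), 40)
  expect_equal(motility_percent(trajs, 5, initial_motility_pct = 80), 50)
  expect_equal(motility_percent(rev(trajs), 5), 40)
  expect_equal(motility_percent(lapply(rep(40, 3), mk), 5,
                                initial_motility_pct = 100), 100)
  expect_error(motility_percent(list(), 5), "nonempty")
  s <- motility_summary(trajs, 5)
  expect_equal(s$n_tracks, 10)
  expect_equal(s$n_motile, 4)
  expect_equal(s$mean_velocity, 40)
})

test_that("erratic-track filter drops direction-scrambled tracks only", {
  smooth <- data.frame(time_s = 0:10, x_um = 3 * (0:10), y_um = 0)
  set.seed(5)
  jitter <- data.frame(time_s = 0:10, x_um = cumsum(rnorm(11)),
                       y_um = cumsum(rnorm(11)))
  kept <- filter_erratic_tracks(list(smooth, jitter), max_circ_var = 0.3)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$x_um, smooth$x_um)
})

test_that("Fisher exact p matches independent enumeration on all margins <= 12", {
  for (r1 in 1:12) for (r2 in 1:12) {
    for (a in 0:r1) {
      c1 <- a + (if (r2 >= 3) 3 else r2)   # one representative column margin
      if (c1 > r1 + r2 || c1 < 1) next
      tab <- matrix(c(a, r1 - a, c1 - a, r2 - (c1 - a)), 2, byrow = TRUE)
      if (any(tab < 0) || min(colSums(tab)) == 0) next
      expect_equal(fisher_exact_2x2(tab), oracle_fisher_p(tab),
                   tolerance = 1e-12)
    }
  }
  # spot checks against the reference implementation
  for (tab in list(matrix(c(0, 5, 5, 0), 2), matrix(c(3, 9, 7, 2), 2),
                   matrix(c(1, 11, 12, 1), 2), matrix(c(6, 6, 6, 6), 2))) {
    expect_equal(fisher_exact_2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher special cases: no-association, transpose symmetry, degeneracy", {
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2)), 2 / 252,
               tolerance = 1e-12)
  tab <- matrix(c(2, 7, 8, 3), 2)
  expect_equal(fisher_exact_2x2(tab), fisher_exact_2x2(t(tab)),
               tolerance = 1e-12)
  expect_warning(p <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "degenerate")
  expect_equal(p, 1)
})

test_that("survival tables find the threshold and the all-or-nothing p-value", {
  rec <- data.frame(
    V0_nL = c(rep(5, 10), rep(100, 10)),
    motility_30min_pct = 80,
    motility_postthaw_pct = c(rep(0, 10), rep(50, 10)),
    velocity_um_s = 60)
  st <- survival_table(rec, 30)
  expect_equal(unname(st$counts["below", ]), c(0, 10))
  expect_equal(unname(st$counts["above", ]), c(10, 0))
  expect_equal(st$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(st$empirical_threshold_nL, 100)
  expect_error(survival_table(rec, 1), "one side")
})

test_that("survival analysis of the generated panel localizes the 30-nL threshold", {
  panel <- gen_survival_panel(experiment_design(), default_geom,
                              default_props, seed = 2)
  expect_true(all(panel$motility_postthaw_pct[panel$V0_nL < 30] == 0))
  st <- survival_table(panel, 30)
  expect_equal(st$empirical_threshold_nL, 30)
  expect_lt(st$p_value, 1e-4)
  # a misplaced analysis threshold weakens the association
  expect_gt(survival_table(panel, 300)$p_value, st$p_value)
})

test_that("cell detection recovers spot centroids and tolerates blank frames", {
  spot <- function(x, y) data.frame(time_s = 0, x_um = x, y_um = y)
  fr <- gen_frames(list(spot(40.3, 22.7)), image_size = c(64, 96),
                   pixel_um = 1, psf_sigma = 1.5, snr = Inf, seed = 1)
  det <- detect_cells_in_frame(fr[[1]], 0.2)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_um - 40.3), 0.1)
  expect_lt(abs(det$y_um - 22.7), 0.1)
  blank <- matrix(0, 32, 32)
  expect_equal(nrow(detect_cells_in_frame(blank)), 0)
  fr2 <- gen_frames(list(spot(20, 20), spot(70, 40)),
                    image_size = c(64, 96), snr = Inf, seed = 1)
  expect_equal(nrow(detect_cells_in_frame(fr2[[1]], 0.2)), 2)
})
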