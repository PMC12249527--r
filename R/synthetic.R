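# Seeded synthetic-data generators for every measurement modality the
# pipeline consumes: bright-field droplet area series, polarized fluorescence
# intensity pairs, sperm trajectories/detections, survival panels, and
# rendered image frames. Each generator is a pure function of (parameters,
# seed); one global seed fans out to per-modality substreams so adding a
# generator never perturbs the others.
#
# The generators emulate the study conditions: initial mean swimming speed
# 66 um/s with 5% SD, 30-minute soak, zero post-thaw survival below 30 nL,
# the constant ~108 um^2/min surface-loss rate, and viscosity roughly
# doubling as droplets shrink. The physiological response to osmotic stress
# is emulated (not modelled mechanistically) by a speed factor
# phi(C) = min(1, (C0/C)^gamma): gamma = 0 disables stress, and the default
# gamma = 4 reproduces the ~40% velocity drop at ~1-nL volumes.

modality_seed <- function(seed, modality) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  (as.integer(seed) %% 1000003L) + 1009L * sum(utf8ToInt(modality))
}

#' Design of a synthetic droplet experiment
#'
#' Parameters shared by the synthetic-data generators. Defaults are the
#' study conditions: a log-spaced volume grid spanning 0.1-1000 nL, a 30-nL
#' survival threshold, 66 um/s initial mean velocity with 5% SD, 30-minute
#' soak, five replicates per volume and modest measurement noise.
#'
#' @param volumes_nL Grid of initial volumes, nL.
#' @param survival_threshold_nL Volume below which no cell survives the
#'   freeze-thaw cycle, nL.
#' @param v0_mean Initial mean swimming speed, um/s.
#' @param v0_sd_frac Between-cell speed SD as a fraction of the mean
#'   (<= 0.05 by design).
#' @param duration_min Soak duration, min.
#' @param replicates Droplets per volume in panel generators.
#' @param area_noise_frac Multiplicative noise on measured footprint areas.
#' @param fp_noise_frac Multiplicative noise on each polarized intensity.
#' @param velocity_noise_frac Noise on panel-level mean velocities.
#' @param immotile_frac Fraction of immotile cells in generated track sets.
#' @param stress_gamma Exponent of the emulated osmotic-stress speed factor
#'   `phi(C) = min(1, (C0/C)^gamma)`; 0 disables stress.
#' @param seed Default integer seed.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(volumes_nL = c(0.1, 0.3, 1, 3, 10, 30, 100,
                                             300, 1000),
                              survival_threshold_nL = 30,
                              v0_mean = 66, v0_sd_frac = 0.05,
                              duration_min = 30, replicates = 5,
                              area_noise_frac = 0.02, fp_noise_frac = 0.02,
                              velocity_noise_frac = 0.05,
                              immotile_frac = 0.1, stress_gamma = 4,
                              seed = 1L) {
  stopifnot(all(volumes_nL > 0), survival_threshold_nL > 0,
            v0_mean > 0, v0_sd_frac >= 0, v0_sd_frac < 1,
            duration_min > 0, replicates >= 1,
            area_noise_frac >= 0, area_noise_frac < 1,
            fp_noise_frac >= 0, fp_noise_frac < 1,
            velocity_noise_frac >= 0, velocity_noise_frac < 1,
            immotile_frac >= 0, immotile_frac < 1, stress_gamma >= 0)
  structure(as.list(environment()), class = "experiment_design")
}

#' Emulated osmotic-stress speed factor
#'
#' `phi(C) = min(1, (C0/C)^gamma)`: the fraction of the viscosity-predicted
#' speed a cell retains after its droplet concentrated from `C0` to `C`.
#' A descriptive emulation device, not a mechanistic model.
#'
#' @param conc_ratio `C/C0 = V0/Vt`, >= 1 under shrinkage. Vectorized.
#' @param gamma Stress exponent (>= 0); 0 disables the effect.
#' @return Factor in `(0, 1]`.
#' @export
stress_factor <- function(conc_ratio, gamma = 4) {
  stopifnot(gamma >= 0, all(conc_ratio > 0))
  pmin(1, conc_ratio^(-gamma))
}

# shared helper: closed-form 30-min droplet endpoint for one volume
droplet_endpoint <- function(V0_nl, duration_min, geom, props) {
  tr <- simulate_shrinkage(V0_nl, duration = duration_min,
                           dt = duration_min, geom = geom, props = props)
  vanished <- is.finite(attr(tr, "vanished_at"))
  if (vanished) {
    list(vanished = TRUE, conc_ratio = Inf, eta = Inf)
  } else {
    S0 <- tr$S_um2[1]
    rate <- surface_shrink_rate(props, geom)
    S_end <- S0 + rate * duration_min
    V_end <- volume_from_surface(S_end, geom)
    cr <- nl_to_um3(V0_nl) / V_end
    lam <- props$eta_s0 / props$eta_w - 1
    list(vanished = FALSE, conc_ratio = cr,
         eta = props$eta_w * (1 + lam * cr))
  }
}

#' Synthetic bright-field droplet footprint-area series
#'
#' Noiseless mean follows the closed-form shrinkage trajectory
#' (`A = S / c_SA`, linear in time); multiplicative Gaussian noise is added
#' at `noise_frac`. If the droplet vanishes within the duration, the series
#' is truncated and flagged via the `vanished_at` attribute.
#'
#' @param V0_nl Initial volume, nL.
#' @param design An [experiment_design()].
#' @param geom A [cap_geometry()].
#' @param props A [medium_properties()].
#' @param dt Sampling interval, min.
#' @param noise_frac Multiplicative noise fraction; defaults to the design's.
#' @param seed Integer seed; defaults to the design's.
#' @return Data frame `time_min`, `area_um2` with attribute `vanished_at`.
#' @export
gen_area_series <- function(V0_nl, design = experiment_design(),
                            geom = cap_geometry(51),
                            props = medium_properties(),
                            dt = 1, noise_frac = design$area_noise_frac,
                            seed = design$seed) {
  tr <- simulate_shrinkage(V0_nl, duration = design$duration_min, dt = dt,
                           geom = geom, props = props)
  A <- area_from_surface(tr$S_um2, geom)
  if (noise_frac > 0) {
    set.seed(modality_seed(seed, "area"))
    A <- A * (1 + stats::rnorm(length(A), sd = noise_frac))
  }
  out <- data.frame(time_min = tr$time_min, area_um2 = A)
  attr(out, "vanished_at") <- attr(tr, "vanished_at")
  out
}

#' Synthetic polarized-fluorescence intensity pairs
#'
#' Forward Perrin model: for each viscosity, `p` from
#' [polarization_from_viscosity()], split a total intensity into
#' `I_par = T (1 + p)/2` and `I_perp = T (1 - p)/2`, and apply independent
#' multiplicative Gaussian noise to each channel. Inverting the noiseless
#' output recovers the viscosities exactly.
#'
#' @param viscosities Vector of true viscosities, cP.
#' @param total_intensity Total emission intensity per measurement (a.u.).
#' @param noise_frac Per-channel multiplicative noise fraction.
#' @param spec A [fluorophore_spec()].
#' @param seed Integer seed.
#' @return Data frame `eta_true`, `I_par`, `I_perp`.
#' @export
gen_fp_series <- function(viscosities, total_intensity = 1000,
                          noise_frac = 0.02, spec = fluorophore_spec(),
                          seed = 1L) {
  stopifnot(all(viscosities > 0), total_intensity > 0,
            noise_frac >= 0, noise_frac < 1)
  p <- polarization_from_viscosity(viscosities, spec)
  I_par <- total_intensity * (1 + p) / 2
  I_perp <- total_intensity * (1 - p) / 2
  if (noise_frac > 0) {
    set.seed(modality_seed(seed, "fp"))
    I_par <- I_par * (1 + stats::rnorm(length(p), sd = noise_frac))
    I_perp <- I_perp * (1 + stats::rnorm(length(p), sd = noise_frac))
  }
  data.frame(eta_true = viscosities, I_par = pmax(I_par, 0),
             I_perp = pmax(I_perp, 0))
}

#' Synthetic sperm tracks and per-frame detections
#'
#' Persistent-random-walk tracks at the speed implied by the droplet's
#' 30-min state: `v = v0 * eta0 / eta(30) * phi(C(30))`, with per-cell
#' speed scatter of `v0_sd_frac` and a configured immotile fraction moving
#' only by sub-micron jitter. Cells start on a coarse grid so tracks do not
#' cross. Ground truth is returned alongside the detections.
#'
#' @param n_cells Number of cells (>= 1).
#' @param V0_nl Initial droplet volume, nL.
#' @param design An [experiment_design()].
#' @param geom A [cap_geometry()].
#' @param props A [medium_properties()].
#' @param gamma Stress exponent; defaults to the design's.
#' @param n_frames Number of frames.
#' @param dt_s Frame interval, s.
#' @param seed Integer seed.
#' @return A list with `frames` (per-frame detection data frames `x_um`,
#'   `y_um`), `tracks` (ground-truth trajectory list), `speeds` (true
#'   per-cell speeds), `v_expected` (noise-free motile speed), `eta_30`
#'   and `conc_ratio`.
#' @export
gen_tracks <- function(n_cells, V0_nl, design = experiment_design(),
                       geom = cap_geometry(51), props = medium_properties(),
                       gamma = design$stress_gamma,
                       n_frames = 25, dt_s = 0.04, seed = design$seed) {
  stopifnot(n_cells >= 1, n_frames >= 2, dt_s > 0)
  ep <- droplet_endpoint(V0_nl, design$duration_min, geom, props)
  v_exp <- if (ep$vanished) 0 else
    design$v0_mean * (props$eta_s0 / ep$eta) *
      stress_factor(ep$conc_ratio, gamma)

  set.seed(modality_seed(seed, "tracks"))
  n_immotile <- round(design$immotile_frac * n_cells)
  motile <- rep(TRUE, n_cells)
  if (n_immotile > 0) motile[sample.int(n_cells, n_immotile)] <- FALSE
  speeds <- ifelse(motile,
                   pmax(0, v_exp * (1 + stats::rnorm(n_cells,
                                                     sd = design$v0_sd_frac))),
                   0)

  # start positions on a coarse grid (50-um pitch): tracks never cross
  ngrid <- ceiling(sqrt(n_cells))
  gx <- ((seq_len(n_cells) - 1) %% ngrid) * 50 + 25
  gy <- ((seq_len(n_cells) - 1) %/% ngrid) * 50 + 25

  times <- (seq_len(n_frames) - 1) * dt_s
  tracks <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    th <- stats::runif(1, 0, 2 * pi) +
      cumsum(c(0, stats::rnorm(n_frames - 1, sd = 0.15)))
    step <- speeds[i] * dt_s
    x <- gx[i] + cumsum(c(0, step * cos(th[-1])))
    y <- gy[i] + cumsum(c(0, step * sin(th[-1])))
    if (!motile[i]) {   # immotile: sub-micron Brownian jitter only
      x <- gx[i] + cumsum(c(0, stats::rnorm(n_frames - 1, sd = 0.05)))
      y <- gy[i] + cumsum(c(0, stats::rnorm(n_frames - 1, sd = 0.05)))
    }
    tracks[[i]] <- new_trajectory(times, x, y, track_id = i)
  }
  frames <- lapply(seq_len(n_frames), function(k) {
    data.frame(x_um = vapply(tracks, function(tr) tr$x_um[k], numeric(1)),
               y_um = vapply(tracks, function(tr) tr$y_um[k], numeric(1)))
  })
  list(frames = frames, tracks = tracks, speeds = speeds,
       v_expected = v_exp, eta_30 = ep$eta, conc_ratio = ep$conc_ratio,
       motile = motile)
}

#' Synthetic survival panel (volume sweep)
#'
#' One record per droplet across the design's volume grid and replicates:
#' post-thaw motility is exactly zero below the survival threshold and rises
#' steeply (logistically in log-volume) above it; 30-min motility is mildly
#' reduced at small volumes; 30-min velocity follows the viscosity-and-stress
#' model, reduced ~40% at ~1-nL volumes relative to the >= 10 nL plateau.
#' All with seeded multiplicative noise.
#'
#' @param design An [experiment_design()].
#' @param geom A [cap_geometry()].
#' @param props A [medium_properties()].
#' @param seed Integer seed.
#' @return Data frame `V0_nL`, `motility_30min_pct`, `motility_postthaw_pct`,
#'   `velocity_um_s`.
#' @export
gen_survival_panel <- function(design = experiment_design(),
                               geom = cap_geometry(51),
                               props = medium_properties(),
                               seed = design$seed) {
  set.seed(modality_seed(seed, "survival"))
  rows <- list()
  for (V0 in design$volumes_nL) {
    ep <- droplet_endpoint(V0, design$duration_min, geom, props)
    phi <- if (ep$vanished) 0 else
      stress_factor(ep$conc_ratio, design$stress_gamma)
    v_mean <- if (ep$vanished) 0 else
      design$v0_mean * (props$eta_s0 / ep$eta) * phi
    for (r in seq_len(design$replicates)) {
      m30 <- 100 * (0.6 + 0.4 * phi) *
        (1 + stats::rnorm(1, sd = design$velocity_noise_frac))
      if (V0 < design$survival_threshold_nL) {
        mpt <- 0
      } else {
        mpt <- 90 * stats::plogis(2.5 * (log10(V0) - log10(40))) *
          (1 + stats::rnorm(1, sd = design$velocity_noise_frac))
        mpt <- max(mpt, 1)   # survivors above threshold stay nonzero
      }
      vel <- max(0, v_mean * (1 + stats::rnorm(1,
                                               sd = design$velocity_noise_frac)))
      rows[[length(rows) + 1]] <- data.frame(
        V0_nL = V0,
        motility_30min_pct = min(100, max(0, m30)),
        motility_postthaw_pct = min(100, mpt),
        velocity_um_s = vel)
    }
  }
  do.call(rbind, rows)
}

#' Render synthetic image frames from tracks
#'
#' Gaussian spots at the track positions on a noisy background, one frame
#' per time point. Spots falling outside the frame are clipped and counted
#' in the `n_clipped` attribute; ground-truth positions are retained in the
#' `positions` attribute.
#'
#' @param tracks List of trajectories (as from [gen_tracks()]).
#' @param image_size `c(rows, cols)` in pixels.
#' @param pixel_um Pixel pitch, um/px.
#' @param psf_sigma Spot standard deviation, px.
#' @param snr Peak amplitude over background-noise SD; `Inf` for noise-free.
#' @param seed Integer seed.
#' @return List of intensity matrices with attributes `positions` (per-frame
#'   true positions, um) and `n_clipped`.
#' @export
gen_frames <- function(tracks, image_size = c(96, 96), pixel_um = 1,
                       psf_sigma = 1.5, snr = 20, seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 8),
            pixel_um > 0, psf_sigma > 0, snr > 0)
  n_frames <- if (length(tracks) > 0) nrow(tracks[[1]]) else 1L
  nr <- image_size[1]; nc <- image_size[2]
  set.seed(modality_seed(seed, "frames"))
  n_clipped <- 0L
  xs <- (seq_len(nc) - 0.5) * pixel_um
  ys <- (seq_len(nr) - 0.5) * pixel_um
  s_um <- psf_sigma * pixel_um
  positions <- vector("list", n_frames)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    img <- if (is.finite(snr))
      matrix(stats::rnorm(nr * nc, sd = 1 / snr), nr, nc)
    else matrix(0, nr, nc)
    pos <- do.call(rbind, lapply(tracks, function(tr)
      c(tr$x_um[k], tr$y_um[k])))
    if (is.null(pos)) pos <- matrix(numeric(0), ncol = 2)
    keep <- pos[, 1] >= 0 & pos[, 1] <= nc * pixel_um &
            pos[, 2] >= 0 & pos[, 2] <= nr * pixel_um
    n_clipped <- n_clipped + sum(!keep)
    pos <- pos[keep, , drop = FALSE]
    for (m in seq_len(nrow(pos))) {
      gx <- exp(-(xs - pos[m, 1])^2 / (2 * s_um^2))
      gy <- exp(-(ys - pos[m, 2])^2 / (2 * s_um^2))
      img <- img + outer(gy, gx)
    }
    frames[[k]] <- img
    positions[[k]] <- pos
  }
  attr(frames, "positions") <- positions
  attr(frames, "n_clipped") <- n_clipped
  frames
}
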