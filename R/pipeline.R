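# End-to-end orchestration: validated run configuration, a simulate step
# writing every synthetic modality, an analyze step turning the written
# files into a machine-readable results list plus figures, and a constants
# table checking every closed-form model constant against its rounded
# published value. All numbers in the results come from module operations;
# this layer only arranges them.

#' Validated run configuration
#'
#' Builds and validates the configuration driving [run_simulate()] and
#' [run_analyze()]. Accepts a flat key-value JSON file and/or direct
#' overrides; every value is pushed through the corresponding constructor so
#' an invalid entry fails fast with the offending key named.
#'
#' @param path Optional path to a flat JSON config file.
#' @param ... Direct overrides of the same keys: `contact_angle_deg`,
#'   `DC0_kg_per_m_s`, `rho_w`, `osmolarity_osm`, `saturation`, `eta_w`,
#'   `eta_s0`, `p0`, `tau_ns`, `M_W`, `fluorophore_density`,
#'   `temperature_K`, `axis_a_um`, `axis_b_um`, `axis_c_um`, `v0_um_per_s`,
#'   `volumes_nL`, `replicates`, `duration_min`, `stress_gamma`, `seed`.
#' @return A list of class `run_config` with validated components `geom`,
#'   `props`, `fluor`, `morph`, `design` and the raw `keys`.
#' @examples
#' cfg <- run_config(saturation = 1)
#' cfg$props$saturation
#' @export
run_config <- function(path = NULL, ...) {
  keys <- list(
    contact_angle_deg = 51, DC0_kg_per_m_s = 1.88e-10, rho_w = 997,
    osmolarity_osm = 0.15, saturation = 0, eta_w = 0.89, eta_s0 = 1.876,
    p0 = 0.5, tau_ns = 3.8, M_W = 376.3, fluorophore_density = 1.0,
    temperature_K = 298.15, axis_a_um = 2.5, axis_b_um = 1.0,
    axis_c_um = 1.5, v0_um_per_s = 66,
    volumes_nL = c(0.1, 0.3, 1, 3, 10, 30, 100, 300, 1000),
    replicates = 5, duration_min = 30, stress_gamma = 4, seed = 1L)
  if (!is.null(path)) {
    file_keys <- jsonlite::read_json(path, simplifyVector = TRUE)
    bad <- setdiff(names(file_keys), names(keys))
    if (length(bad) > 0)
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    keys[names(file_keys)] <- file_keys
  }
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(keys))
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  keys[names(overrides)] <- overrides

  wrap <- function(key, expr) {
    tryCatch(expr, error = function(e)
      stop("invalid config value for `", key, "`: ", conditionMessage(e),
           call. = FALSE))
  }
  geom <- wrap("contact_angle_deg", cap_geometry(keys$contact_angle_deg))
  props <- wrap("DC0_kg_per_m_s/rho_w/osmolarity_osm/saturation",
                medium_properties(rho_w = keys$rho_w,
                                  DC0 = keys$DC0_kg_per_m_s,
                                  osmolarity = keys$osmolarity_osm,
                                  saturation = keys$saturation,
                                  eta_w = keys$eta_w,
                                  eta_s0 = keys$eta_s0))
  fluor <- wrap("p0/tau_ns/M_W/fluorophore_density/temperature_K",
                fluorophore_spec(p0 = keys$p0, tau_ns = keys$tau_ns,
                                 M_W = keys$M_W,
                                 density = keys$fluorophore_density,
                                 T_K = keys$temperature_K))
  morph <- wrap("axis_a_um/axis_b_um/axis_c_um",
                sperm_morphology(keys$axis_a_um, keys$axis_b_um,
                                 keys$axis_c_um))
  design <- wrap("volumes_nL/replicates/duration_min/stress_gamma/seed",
                 experiment_design(volumes_nL = keys$volumes_nL,
                                   v0_mean = keys$v0_um_per_s,
                                   duration_min = keys$duration_min,
                                   replicates = keys$replicates,
                                   stress_gamma = keys$stress_gamma,
                                   seed = keys$seed))
  structure(list(geom = geom, props = props, fluor = fluor, morph = morph,
                 design = design, keys = keys),
            class = "run_config")
}

assert_config <- function(config) {
  if (!inherits(config, "run_config"))
    stop("`config` must be a run_config object", call. = FALSE)
  config
}

#' Write all synthetic modalities to a directory
#'
#' Generates and writes, for the configured volume grid: per-volume
#' footprint-area series (`area_V<v>.csv`), a survival panel
#' (`survival.csv`), a 20-droplet fluorescence-polarization panel
#' (`fp_panel.csv`), per-volume track files (`tracks_V<v>.csv`), and a
#' `manifest.json` recording parameters and seed. Identical config and seed
#' give identical bytes.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; defaults to the config's.
#' @return Invisibly, the manifest list.
#' @export
run_simulate <- function(config, out_dir, seed = config$design$seed) {
  assert_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- config$design; design$seed <- seed

  for (V0 in design$volumes_nL) {
    ser <- gen_area_series(V0, design, config$geom, config$props, seed = seed)
    write_csv_plain(ser, file.path(out_dir, sprintf("area_V%g.csv", V0)))
  }

  panel <- gen_survival_panel(design, config$geom, config$props, seed = seed)
  write_csv_plain(panel, file.path(out_dir, "survival.csv"))

  fp <- gen_fp_panel(design, config$geom, config$props, config$fluor,
                     seed = seed)
  write_csv_plain(fp, file.path(out_dir, "fp_panel.csv"))

  for (V0 in design$volumes_nL) {
    tk <- gen_tracks(20, V0, design, config$geom, config$props, seed = seed)
    write_trajectories_csv(tk$tracks,
                           file.path(out_dir, sprintf("tracks_V%g.csv", V0)))
  }

  manifest <- list(keys = config$keys, seed = seed,
                   files = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Two-method viscometry panel
#'
#' Generates the cross-method comparison panel: `n_droplets` droplets with
#' initial volumes log-spaced over 0.022-10 nL, reaching down to about 1.1
#' times the volume that vanishes within the soak. Over that range the
#' 30-min viscosities span roughly 2-50 cP, a spread comfortably above the
#' per-droplet polarization error so the two estimators can be compared
#' meaningfully. Each droplet contributes its true volume ratio and a noisy
#' polarized intensity pair generated from the same viscosity through the
#' forward Perrin model. Droplets that vanish within the soak are dropped.
#'
#' @param design An [experiment_design()].
#' @param geom A [cap_geometry()].
#' @param props A [medium_properties()].
#' @param fluor A [fluorophore_spec()].
#' @param n_droplets Panel size.
#' @param seed Integer seed.
#' @return Data frame `V0_nL`, `volume_ratio`, `eta_true`, `I_par`,
#'   `I_perp`.
#' @export
gen_fp_panel <- function(design, geom = cap_geometry(51),
                         props = medium_properties(),
                         fluor = fluorophore_spec(), n_droplets = 20,
                         seed = design$seed) {
  V0 <- 10^seq(log10(0.022), log10(10), length.out = n_droplets)
  ep <- lapply(V0, droplet_endpoint, duration_min = design$duration_min,
               geom = geom, props = props)
  ok <- !vapply(ep, `[[`, logical(1), "vanished")
  V0 <- V0[ok]
  eta <- vapply(ep[ok], `[[`, numeric(1), "eta")
  cr <- vapply(ep[ok], `[[`, numeric(1), "conc_ratio")
  fp <- gen_fp_series(eta, noise_frac = design$fp_noise_frac, spec = fluor,
                      seed = seed)
  data.frame(V0_nL = V0, volume_ratio = cr, eta_true = eta,
             I_par = fp$I_par, I_perp = fp$I_perp)
}

#' Analyze a directory of measurement files
#'
#' Reads the CSV modalities written by [run_simulate()] (or real data in the
#' same dialects) and computes the full results set: the two surface-shrink
#' rates, a D*C0 estimate from the smallest-volume area series, the
#' concentration-rate curve, the two-method viscosity comparison, the
#' measured-vs-predicted velocity profile with its physiological deficits,
#' motility/survival with Fisher's exact p, and the model constants. Writes
#' `results.json` and, optionally, the four diagnostic figures.
#'
#' @param config A [run_config()].
#' @param input_dir Directory holding the input CSVs.
#' @param out_dir Output directory; defaults to `input_dir`.
#' @param plots If `TRUE`, also write ggplot figures (PDF).
#' @return The results list, invisibly; also written as JSON.
#' @export
run_analyze <- function(config, input_dir, out_dir = input_dir,
                        plots = FALSE) {
  assert_config(config)
  if (!dir.exists(input_dir))
    stop("input directory not found: ", input_dir, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- config$geom; props <- config$props
  design <- config$design

  area_files <- list.files(input_dir, pattern = "^area_V.*\\.csv$",
                           full.names = TRUE)
  surv_file <- file.path(input_dir, "survival.csv")
  fp_file <- file.path(input_dir, "fp_panel.csv")
  if (length(area_files) == 0 && !file.exists(surv_file) &&
      !file.exists(fp_file))
    stop("no recognized input files in ", input_dir, call. = FALSE)

  res <- list(constants = constants_list(config))

  if (length(area_files) > 0) {
    # estimate D*C0 from the smallest droplet (largest relative shrinkage)
    v_of <- function(f) as.numeric(sub("^area_V(.*)\\.csv$", "\\1",
                                       basename(f)))
    f_min <- area_files[which.min(vapply(area_files, v_of, numeric(1)))]
    est <- estimate_DC0(read_area_series(f_min), geom, props)
    res$DC0_estimate <- est[c("DC0", "se", "dAdt", "dSdt")]
  }

  # concentration-rate curve at fixed solute amount (the steep-knee law)
  V_grid <- 10^seq(-1, 3, length.out = 41)
  res$concentration_rate <- list(
    V_nL = V_grid,
    dCdt = concentration_rate(V_grid, geom, props, n0 = 1e-9))

  fp_panel <- NULL
  if (file.exists(fp_file)) {
    fp_panel <- utils::read.csv(fp_file)
    p <- polarization(fp_panel$I_par, fp_panel$I_perp)
    eta_fp <- perrin_viscosity(pmin(pmax(p, 1e-6),
                                    config$fluor$p0 * 0.999999),
                               config$fluor)
    eta_vr <- viscosity_from_volume_ratio(fp_panel$volume_ratio, 1, props)
    res$viscometry <- list(V0_nL = fp_panel$V0_nL, eta_fp = eta_fp,
                           eta_volume_ratio = eta_vr,
                           correlation = stats::cor(eta_fp, eta_vr))
  }

  panel <- NULL
  if (file.exists(surv_file)) {
    panel <- read_survival_records(surv_file)
    st <- survival_table(panel, design$survival_threshold_nL)
    agg <- stats::aggregate(panel[c("motility_30min_pct",
                                    "motility_postthaw_pct",
                                    "velocity_um_s")],
                            by = list(V0_nL = panel$V0_nL), FUN = mean)
    eta30 <- vapply(agg$V0_nL, function(v)
      droplet_endpoint(v, design$duration_min, geom, props)$eta, numeric(1))
    v_pred <- ifelse(is.finite(eta30),
                     predict_velocity(design$v0_mean, props$eta_s0, eta30), 0)
    deficit <- ifelse(v_pred > 0,
                      physiological_deficit(agg$velocity_um_s, v_pred), 0)
    res$survival <- list(counts = as.vector(st$counts),
                         fisher_p = st$p_value,
                         empirical_threshold_nL = st$empirical_threshold_nL,
                         by_volume = c(as.list(agg),
                                       list(v_predicted = v_pred,
                                            deficit = deficit)))
  }

  jsonlite::write_json(res, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (plots) write_figures(res, out_dir)
  invisible(res)
}

write_figures <- function(res, out_dir) {
  gg_save <- function(p, name) {
    ggplot2::ggsave(file.path(out_dir, name), p, width = 6, height = 4)
  }
  cr <- data.frame(V = res$concentration_rate$V_nL,
                   r = res$concentration_rate$dCdt)
  gg_save(ggplot2::ggplot(cr, ggplot2::aes(V, r)) +
            ggplot2::geom_line() + ggplot2::scale_x_log10() +
            ggplot2::scale_y_log10() +
            ggplot2::labs(x = "initial volume (nL)",
                          y = "dC/dt (mol m^-3 min^-1)",
                          title = "Concentration-rate leap in small droplets"),
          "concentration_rate.pdf")
  if (!is.null(res$viscometry)) {
    vs <- data.frame(fp = res$viscometry$eta_fp,
                     vr = res$viscometry$eta_volume_ratio)
    gg_save(ggplot2::ggplot(vs, ggplot2::aes(vr, fp)) +
              ggplot2::geom_point() +
              ggplot2::geom_abline(slope = 1, intercept = 0,
                                   linetype = "dashed") +
              ggplot2::labs(x = "volume-ratio viscosity (cP)",
                            y = "FP viscosity (cP)",
                            title = "Two-method viscometry"),
            "viscometry.pdf")
  }
  if (!is.null(res$survival)) {
    bv <- as.data.frame(res$survival$by_volume)
    gg_save(ggplot2::ggplot(bv, ggplot2::aes(V0_nL)) +
              ggplot2::geom_line(ggplot2::aes(y = motility_30min_pct,
                                              colour = "30 min")) +
              ggplot2::geom_line(ggplot2::aes(y = motility_postthaw_pct,
                                              colour = "post-thaw")) +
              ggplot2::scale_x_log10() +
              ggplot2::labs(x = "initial volume (nL)", y = "% motility",
                            colour = NULL, title = "Survival vs volume"),
            "survival.pdf")
    gg_save(ggplot2::ggplot(bv, ggplot2::aes(V0_nL)) +
              ggplot2::geom_line(ggplot2::aes(y = velocity_um_s,
                                              colour = "measured")) +
              ggplot2::geom_line(ggplot2::aes(y = v_predicted,
                                              colour = "viscosity model")) +
              ggplot2::scale_x_log10() +
              ggplot2::labs(x = "initial volume (nL)",
                            y = "velocity (um/s)", colour = NULL,
                            title = "Measured vs predicted velocity"),
            "velocity.pdf")
  }
  invisible(NULL)
}

constants_list <- function(config) {
  geom <- config$geom; props <- config$props
  list(
    c_S = geom$c_S, c_V = geom$c_V, c_SA = geom$c_SA, c_VS = geom$c_VS,
    c_VA = geom$c_VA,
    flux_balance_factor = flux_balance_factor(geom),
    shrink_rate_DC0_um2_min = surface_shrink_rate(props, geom),
    shrink_rate_dAdt_um2_min = shrink_rate_from_dAdt(-88.4, geom),
    lambda_c0 = props$eta_s0 / props$eta_w - 1,
    eta_s0_cP = viscosity_from_volume_ratio(1, 1, props),
    K_beta_printed = shape_factor(2.08),
    K_beta_axes = shape_factor(axis_ratio(config$morph)),
    beta_axes = axis_ratio(config$morph),
    dCdS_prefactor_1e9mol = dCdt_prefactor(1e-9, geom))
}

#' Table of closed-form model constants
#'
#' Computes every closed-form constant of the model from the configuration
#' and tabulates it next to its rounded published reference value with the
#' relative deviation. Useful as a quick verification surface.
#'
#' @param config A [run_config()].
#' @return Data frame with columns `name`, `computed`, `reference`,
#'   `rel_dev`.
#' @examples
#' run_constants(run_config())
#' @export
run_constants <- function(config = run_config()) {
  assert_config(config)
  k <- constants_list(config)
  ref <- c(c_S = 2.329, c_V = 0.378, c_SA = 1.228, c_VS = 0.106,
           c_VA = 0.145, flux_balance_factor = 9.538,
           shrink_rate_DC0_um2_min = -108.35,
           shrink_rate_dAdt_um2_min = -108.5,
           lambda_c0 = 1.108, eta_s0_cP = 1.876,
           K_beta_printed = 1.22, K_beta_axes = 1.22, beta_axes = 2.08,
           dCdS_prefactor_1e9mol = -1.4e-8)
  nm <- names(ref)
  computed <- vapply(nm, function(n) k[[n]], numeric(1))
  data.frame(name = nm, computed = computed, reference = unname(ref),
             rel_dev = abs(computed - ref) / abs(ref), row.names = NULL)
}
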