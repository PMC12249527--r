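# Independent oracles used across the suite. Each re-derives its quantity
# by a route different from the package implementation.

# Fisher exact two-sided p by direct log-binomial enumeration (lchoose,
# not dhyper): sum over all tables with the observed margins of the
# probabilities not exceeding the observed table's.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  a_vals <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, a_vals) + lchoose(r2, c1 - a_vals) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[a_vals == tab[1, 1]]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Forward Perrin model written out from scratch (SI arithmetic only):
# polarization of a fluorophore of molar volume MW/rho at viscosity eta_cp.
oracle_perrin_p <- function(eta_cp, p0 = 0.5, tau_ns = 3.8, M_W = 376.3,
                            rho_g_cm3 = 1, T_K = 298.15) {
  eta <- eta_cp * 1e-3                            # Pa s
  Vmol <- (M_W / 1000) / (rho_g_cm3 * 1000)       # m^3 / mol
  tau_r <- eta * Vmol / (8.314 * T_K)             # s
  1 / (1 / 3 + (1 / p0 - 1 / 3) * (1 + tau_ns * 1e-9 / tau_r))
}

# Closed-form critical volume: initial volume whose concentration rises by
# `factor` in `duration` minutes given a constant surface loss rate.
oracle_critical_volume <- function(duration, factor, rate_um2_min, c_VS) {
  loss <- abs(rate_um2_min) * duration
  S0 <- loss / (1 - factor^(-2 / 3))
  c_VS * S0^1.5 / 1e6                             # nL
}

# Points on a circle of radius r walked at angular rate omega.
circular_track <- function(r, omega, dt, n) {
  t <- (seq_len(n) - 1) * dt
  data.frame(time_s = t, x_um = r * cos(omega * t), y_um = r * sin(omega * t))
}

default_geom <- cap_geometry(51)
default_props <- medium_properties()
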