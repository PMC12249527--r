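---
title: "Why cells die in nanoliter droplets: the models behind nanodrop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why cells die in nanoliter droplets: the models behind nanodrop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodrop)
```

## The problem

Cryopreserving a handful of sperm cells — sometimes a single cell — forces
the sample into nanoliter aqueous droplets deposited under a protective oil
layer. Cells in such droplets swim normally at first (about 66 um/s on
average) but slow dramatically within 30 minutes, and below roughly 30 nL
none survive a freeze–thaw cycle. `nanodrop` implements the biophysical
chain that explains this: water diffuses from the droplet into the oil, the
droplet shrinks at a constant surface rate, solutes concentrate with a
violently volume-dependent rate, viscosity climbs, and the cells slow — more
than viscosity alone can account for, implicating osmotic stress.

## Droplet geometry

A sessile droplet with contact angle $\alpha$ is an ideal spherical cap of
curvature radius $R$. Its curved surface area $S$ (the base disk is in
contact with glass and exchanges no water), footprint area
$A = \pi (R\sin\alpha)^2$ (the quantity a microscope measures) and volume
$V$ satisfy

$$S = 2\pi(1-\cos\alpha)R^2,\qquad
V = \tfrac{\pi}{3}(2+\cos\alpha)(1-\cos\alpha)^2 R^3,$$

from which $S = c_{SA} A$, $V = c_{VS} S^{3/2}$ and $V = c_{VA} A^{3/2}$.
At the measured $\alpha = 51^\circ$:

```{r}
cap_geometry(51)
```

Coefficients are always computed from $\alpha$ at full precision; the
rounded 3-figure values that circulate (2.329, 0.378, 1.228, 0.106, 0.145)
are used only as test expectations at 0.5% relative tolerance. An empirical
calibration of the volume model against injected known volumes reportedly
gives $V \approx 0.143\,A^{1.57}$, close to the ideal $3/2$ exponent; the
package implements only the ideal cap (the small deviation is attributable
to contact-angle measurement accuracy), and no gravity-flattened shapes:
at these volumes the Bond number is negligible.

## Water-loss kinetics

Fick's first law for quasi-steady diffusion out of the cap, integrated with
far-field conditions ($S_\infty \gg S$, $C_\infty \approx 0$), gives an
interfacial mass flux $j = \sqrt{c_S}\,(1-\sigma)\,DC_0/\sqrt{S}$ and —
combined with $dV/dS = \tfrac{3}{2} c_{VS}\sqrt{S}$ — a **size-independent**
surface shrink rate

$$\frac{dS}{dt} = -\frac{\sqrt{c_S}}{\tfrac{3}{2}c_{VS}}
\frac{(1-\sigma)\,DC_0}{\rho_w}.$$

Here $DC_0$ is the product of the diffusivity of water in oil and the
interfacial equilibrium concentration (only the product is identifiable;
default $1.88\times10^{-10}$ kg m$^{-1}$ s$^{-1}$), $\rho_w = 997$
kg/m$^3$, and $\sigma \in [0,1]$ is the oil-saturation fraction.
Saturation enters linearly because Fick's law is linear in the
concentration difference; $\sigma = 1$ (water-saturated oil) nulls the
gradient and freezes every dynamic quantity — the rescue strategy, exactly.

Two numerical notes:

* The geometric factor $\sqrt{c_S}/(\tfrac32 c_{VS})$ evaluates to 9.559 at
  $51^\circ$. Its widely quoted rounding 9.538 is the quotient of the two
  intermediate constants *after* rounding them to 1.526 and 0.160; the
  package always carries full precision, giving a default shrink rate of
  $-108.1\ \mu m^2/\min$ (bright-field route: $c_{SA}\times(-88.4) =
  -108.5\ \mu m^2/\min$; the routes agree within 0.4%).
* Because the rate is constant, $S(t)$ is exactly linear and
  `simulate_shrinkage()` is closed-form; `dt` only controls output
  sampling and there is no solver error to manage. Trajectories truncate
  at the vanishing time $S_0/|dS/dt|$.

Solute is conserved: $C(t) = n_0/V(t)$. By default $n_0 =$ osmolarity
$\times V_0$ with osmolarity 0.15 Osm/L, which is physically consistent
across all volumes; the blanket value $n_0 = 10^{-9}$ mol sometimes quoted
for "small nanoliter volumes" equals that default only near 6–7 nL and is
available as an explicit override. At fixed $n_0$ the concentration rate
obeys

$$\frac{dC}{dt} = -\tfrac{3}{2}\frac{n_0}{c_{VS}}S^{-5/2}\frac{dS}{dt}
\;\propto\; V^{-5/3},$$

flat above ~30 nL and explosive below — the observed all-or-nothing
survival threshold. The prefactor of the popular nL-based form
($\approx 100\,V_{nL}^{-5/3}$) cannot be reconstructed dimensionally from
the stated $n_0$ and unit conventions, so the package asserts only the
exponent and monotone shape, never that prefactor.

`estimate_DC0()` inverts the shrinkage law from a measured
footprint-area series by least squares, propagating the slope's standard
error through the constant factors. Parameter recovery is demonstrated on
0.1-nL droplets: over 30 minutes they lose ~33% of their footprint area,
so a 5% area noise still leaves a well-determined slope (median relative
error ~5% across 200 replicates, 31 points each). For droplets of 1 nL and
larger the 30-minute area change (~7%) is of the same order as that noise
and no slope estimator would do materially better — shrink-rate metrology
belongs in the small-droplet regime.

## Two viscometry routes

**Volume ratio (bright field).** For ionic solutions
$\eta_s/\eta_w = 1 + \Lambda C$. $\Lambda$ and $C$ are not separately
identifiable, but their product at the initial state is pinned by the two
measured viscosities: $\lambda_{C0} = \eta_{s0}/\eta_w - 1 =
1.876/0.89 - 1 \approx 1.108$. Since $C \propto V_0/V_t$,

$$\eta_t = \eta_w\left(1 + \lambda_{C0}\,\frac{V_0}{V_t}\right).$$

**Perrin fluorescence polarization.** The polarization
$p = (I_\parallel - I_\perp)/(I_\parallel + I_\perp)$ of fluorescein
(intrinsic polarization $p_0 = 0.5$, lifetime $\tau = 3.8$ ns, molar
volume 376.3 cm$^3$/mol) reports the rotational correlation time
$\tau_r = \eta V_{mol}/(R_{gas}T)$ through
$1/p - 1/3 = (1/p_0 - 1/3)(1 + \tau/\tau_r)$, inverted as

$$\eta = \tau R_{gas} T \frac{\rho}{M_W}
\frac{1/p_0 - 1/3}{1/p - 1/p_0}.$$

This inversion is the unique arrangement consistent with the Perrin
relation (verified by the forward/inverse roundtrip test). Temperature is
fixed at 298.15 K by default but exposed. No instrument G-factor is
modeled; intensities are assumed corrected. $\eta$ grows strictly with
$p$ and diverges as $p \to p_0$.

**Error analysis for the cross-method panel.** With 2% multiplicative
noise on each intensity channel, the polarization error is approximately
$\delta p \approx \sqrt{2}\cdot 0.02/2 \approx 0.014$ *absolute*. At the
small polarizations of dilute media ($p \approx 0.04$–0.1) this maps to a
20–35% relative error on a single-droplet Perrin viscosity. A meaningful
correlation between the two estimators therefore needs a between-droplet
viscosity spread several times that error — about a decade. The
`gen_fp_panel()` comparison panel spans initial volumes 0.022–10 nL:
its smallest droplets sit ~10% above the volume that vanishes within the
30-minute soak, so their 30-minute viscosities reach ~50 cP while the
largest stay near 1.9 cP. Over that spread the two routes correlate
$> 0.99$; confined to 0.05–10 nL ($\eta$ 1.9–4 cP) no estimator could
reach 0.95 under the stated noise.

The macroscopic reference measurement is a two-speed rotational rheometer
read out as a two-point Bingham fit (`bingham_two_point()`): yield stress
from the intercept, plastic viscosity from the slope, negative intercepts
flagged non-physical.

## Swimming at low Reynolds number

The cell body is a tri-axial ellipsoid with semi-axes $a = 2.5$,
$b = 1.0$, $c = 1.5$ um moving along $a$. Stokes drag is

$$F = 6\pi\eta v \sqrt{bc}\,K(\beta),\qquad
\beta = \frac{a}{\sqrt{bc}},$$

with the prolate shape factor $K(\beta)$ of the standard ellipsoid drag
solution, $K(1) = 1$. Two deliberate readings of ambiguous typography:
the transverse length scale is $\sqrt{bc}$, not the product $bc$ (the
product has dimensions of area and fails the sphere limit, which
$\sqrt{bc}$ reproduces exactly), and the same geometric-mean convention
defines $\beta$. From the printed axes $\beta = 2.04$; the published
rounding $\beta \approx 2.08$ is also honoured where that exact value is
being reproduced ($K(2.08) = 1.220$; both round to 1.22). Oblate shapes
($\beta < 1$) are rejected rather than extended — the drag formula used
is the prolate branch only.

With constant flagellar thrust, drag balance gives the morphology-free
prediction $v = v_0\,\eta_0/\eta_t$. The **physiological deficit**
$v_{meas}/v_{pred}$ then isolates what viscosity cannot explain: 1 means
purely viscous slowdown; values below 1 quantify the osmotic-stress
component.

## What the synthetic data emulate — and what they do not

All generators are pure functions of (parameters, seed); the global seed
fans out to per-modality substreams, so adding a modality never perturbs
another. They emulate: the 66 um/s initial speed with ≤5% SD, the constant
surface-loss rate, the 30-minute soak, zero post-thaw survival below
30 nL with a steep logistic rise above, and the ~40% velocity drop at
~1-nL volumes.

The osmotic-stress response is a descriptive device, not a mechanism:
$\phi(C) = \min(1, (C_0/C)^{\gamma})$ multiplies the viscosity-predicted
speed, with $\gamma = 4$ chosen once from the headline observation — at
1 nL the 30-minute concentration ratio is 1.12 and the viscosity factor
0.94, so $0.94\times1.12^{-4} \approx 0.60$, the reported ~40% drop. The
same $\gamma$ leaves the deficit at 0.91 for 10-nL droplets and pushes it
below 0.81 for 3 nL and smaller, reproducing the "agreement at large
volumes, growing gap below" pattern. $\gamma = 0$ switches stress off.

Tracks are persistent random walks started on a 50-um grid, so they do not
cross; the deterministic greedy linker is exact in this regime. Real
microscopy adds crossing paths, flagellar shape, detection noise and
drift, none of which are rendered — passing tests demonstrate the
analysis chain, not tracker robustness on hard video. Freeze–thaw physics
is likewise not simulated: post-thaw outcomes are generated directly from
the volume threshold, encoding the causal claim without inventing
cryobiology.

Replicates default to 5 per volume (reported only as a lower bound in the
source experiments); the volume grid defaults to nine log-spaced points
over 0.1–1000 nL.

## Numerical and design choices

* Units: um/um²/um³ and nL, minutes, cP at every interface; SI only inside
  flux and drag conversions, each through a single named constant
  (`1 m²/s = 6e13 um²/min`, `1 cP = 1e-3 Pa s`), unit-tested.
* Angles in degrees at the interface, converted once.
* `critical_volume()` brackets on log-volume and bisects the closed-form
  concentration ratio to `tol = 1e-12`; a vanished droplet counts as an
  infinite ratio.
* The motile/immotile threshold defaults to 5 um/s — an order of magnitude
  below the typical swimming speed; boundary speeds count as motile. The
  erratic-movement filter (step-direction circular variance) exists but is
  off by default, since no operational definition is established.
* Fisher's exact test enumerates the hypergeometric support directly
  (two-sided, probabilities ≤ observed with the customary 1e-7 relative
  slack); zero-margin tables return p = 1 with a warning.
* Tracker ties break closest-pair-first, then by track and detection
  index: results are independent of input order.
* Problem sizes in the shipped tests: panels of 20 droplets, track sets of
  25–250 cells over 25 frames, 200-replicate recovery studies — all chosen
  so the statistical assertions have comfortable sampling margins while
  the whole suite stays fast.

## Limitations

The model is quasi-steady, isothermal and gravity-free; no spatially
resolved diffusion in the oil, no evaporation from the oil surface, no
temperature dependence of $DC_0$, no ice physics. The linear
solute-viscosity law is extrapolated well beyond its dilute regime for
near-vanishing droplets. The stress response $\phi$ is an emulation; the
package diagnoses a physiological residual but does not model its
mechanism. The image front-end (thresholding plus 4-connected components)
is deliberately minimal.
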