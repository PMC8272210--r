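---
title: "From relaxation traces to activation energies: the lfnmr methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From relaxation traces to activation energies: the lfnmr methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfnmr)
```

## The physical picture

A starch-stabilized oil-in-water emulsion contains two essentially
independent proton pools: the oil droplets and the aqueous (starch paste)
phase. In a low-field time-domain NMR experiment each pool relaxes with
its own spin-lattice time $T_1$ and spin-spin time $T_2$, so
inversion-recovery and CPMG measurements both show two exponential
components. The short components ($T_{11}$, $T_{21}$) belong to the oil
phase, the long ones ($T_{12}$, $T_{22}$) to the water phase; that
ordering is the phase-assignment rule used throughout.

At the molecular level the relaxation rates are controlled by the mean
rotational correlation time $\tau_c$ — the average time for a molecule to
rotate by one radian. For dipolar relaxation with a single correlation
time the Bloembergen–Purcell–Pound (BPP) model gives

$$R_1 = \frac{1}{T_1} = \frac{6}{20}K\left[
  \frac{\tau_c}{1+(\omega\tau_c)^2} +
  \frac{4\tau_c}{1+(2\omega\tau_c)^2}\right],$$

$$R_2 = \frac{1}{T_2} = \frac{3}{20}K\left[3\tau_c +
  \frac{5\tau_c}{1+(\omega\tau_c)^2} +
  \frac{2\tau_c}{1+(2\omega\tau_c)^2}\right],$$

with $\omega = 2\pi f$ the angular Larmor frequency (default
$f = 15\,\mathrm{MHz}$) and
$K = (\mu_0^2/16\pi^2)\,\gamma^4(h/2\pi)^2/r_0^6$ a lumped dipolar
constant. All physical constants are CODATA 2018 values and live in one
table (`codata_constants()`); they are data, not magic numbers.

Rotation is thermally activated, so the correlation time follows the
Arrhenius law $\tau_c = \tau_0\exp(\Delta E_a/RT)$. The analysis chain is
therefore: fit two components per temperature, assign phases, convert
each phase's $(T_1, T_2)$ pair into $\tau_c$, and regress
$\ln\tau_c$ on $1/T$ — the slope times $R$ is the activation energy
$\Delta E_a$ of rotational motion in that phase, reported in kJ/mol.

## Extracting the correlation time: why the ratio route is the default

Evaluating absolute BPP rates needs $K$, i.e. the effective internuclear
distance $r_0$, which is not measurable in this kind of experiment. The
package therefore defaults to the **ratio method**: $R_2/R_1 = T_1/T_2$
is independent of $K$,

$$\frac{R_2}{R_1} = \frac{1}{2}\,
  \frac{3 + 5/(1+x^2) + 2/(1+4x^2)}{1/(1+x^2) + 4/(1+4x^2)},
  \qquad x = \omega\tau_c,$$

is strictly increasing in $\tau_c$ and approaches 1 in the
extreme-narrowing limit $x \ll 1$, so the inversion
(`tau_c_from_ratio()`) has a unique root, located by bisection on
$\log\tau_c$ to relative tolerance $10^{-10}$.

An alternative mode inverts the absolute $R_1$ (`tau_c_from_r1()`),
which needs $r_0$ (default $1.8\times10^{-10}\,$m, a typical
intramolecular proton pair) and a branch choice, because $R_1$ peaks at
$\omega\tau_c \approx 0.62$ and every attainable rate has a fast- and a
slow-motion root. The branch must be given explicitly; a silent default
would let the code pick the wrong physics.

Noise can push a measured $T_1/T_2$ ratio slightly below the physical
minimum of 1 (typically at the hottest temperatures, where both times
converge). Ratios in $[0.9, 1)$ are clamped to $1 + 10^{-9}$ and flagged
in the output rather than failing the whole series; ratios below 0.9
indicate pathology and abort. The clamp keeps noisy high-temperature
points in the pipeline without hiding them — the flags are carried in
the result's `tau_c` table.

## Multiexponential fitting

Multiexponential decay fitting is notoriously ill-conditioned, so the
fitters are built for reproducibility:

* **Variable projection.** For fixed time constants the amplitudes enter
  the model linearly and are solved exactly (`lm.fit`); the nonlinear
  search runs only over $\log T_i$. The inversion-recovery model is
  reparameterized as $M(\tau) = \sum_i b_i(1/(2\alpha) - e^{-\tau/T_i})$
  with $b_i = 2\alpha M_0 p_i$, which makes $\sum_i p_i = 1$ hold by
  construction and keeps the problem linear in $b$ for fixed $\alpha$.
* **Deterministic initialization.** A log-spaced grid of candidate time
  constants over $[\min(t)/10,\ 10\max(t)]$ is scanned exhaustively (all
  ascending tuples); the best few starts are refined with `nlminb` under
  the same bounds. No random restarts, so a given trace always yields
  the same fit.
* **Inversion efficiency.** $\alpha$ is fixed at 1 (ideal 180° pulse) by
  default; `fit_alpha = TRUE` profiles it over $[0.8, 1]$ for imperfect
  inversion.
* **Weights.** Unit weights by default; if the trace carries a
  `noise_sigma`, rows are inverse-variance weighted (with a single
  scalar sigma this leaves the estimates unchanged, but a per-point
  sigma does not).
* **Model size.** Two components is the default everywhere — the
  two-phase interpretation of an emulsion, and the model actually
  reported per temperature. `select_n_components()` offers an opt-in
  AICc comparison (ties toward fewer components); the mean squared
  residual is floored at $(10^{-9}\max|y|)^2$ so that exactly nested
  noiseless fits compare as ties rather than by floating-point dust.
  Fits whose adjacent time constants differ by less than 20% warn that
  the components have effectively collapsed.
* **No inverse Laplace transform.** Discrete components only; continuous
  $T_2$ distributions are a different instrument tradition and out of
  scope.

Failure is explicit: non-convergence is reported in the `converged`
flag, never patched over; a CPMG trace that does not decay overall is
rejected before fitting.

## The synthetic-data generator

No raw traces are publicly deposited for this kind of experiment, so the
package carries a simulator that is itself first-class, tested code. It
emulates a 15 MHz instrument measuring a two-pool emulsion from 0 to
90 °C: per-pool correlation times follow the Arrhenius law, rates follow
BPP, inversion-recovery and CPMG traces are sampled on timing grids
auto-adjusted per temperature to span $[0.1\min T,\ 4\max T]$ of the
true time constants (log-spaced delays for inversion recovery; a linear
echo train capped at 1000 echoes for CPMG), and i.i.d. Gaussian noise of
standard deviation $M_0/(\mathrm{SNR}\sqrt{n_\mathrm{acc}})$ is added —
SNR is defined against single-shot noise and the default five
accumulations average it down by $\sqrt 5$. Every trace is a
deterministic function of (seed, temperature, sequence), so identical
specs give bit-identical datasets. An optional uniform temperature
jitter (e.g. ±0.5 °C, the realistic regulation error) is off by
default. The pools do not exchange magnetization: cross-relaxation
between oil and water protons is deliberately not modelled, matching
the independent-phases reading of the data.

The `emulsion_preset()` parameterization was chosen once, from physical
reasoning, and is documented as an approximate regime rather than ground
truth for any real sample:

* oil: $\Delta E_a = 25$ kJ/mol, $\tau_0 = 5.4\times10^{-13}$ s,
  $K = 1.2\times10^{10}\,\mathrm{s}^{-2}$;
* water: $\Delta E_a = 15$ kJ/mol, $\tau_0 = 1.1\times10^{-11}$ s,
  $K = 1.5\times10^{9}\,\mathrm{s}^{-2}$;
* proton fractions 0.2 / 0.8, the 1/4 oil-to-water composition.

These values put the oil $T_2$ in the tens of milliseconds and the water
$T_2$ in the hundreds of milliseconds across 0–90 °C (the regimes seen
in starch emulsions at 15 MHz), keep the two $T_1$ components resolvable
(ratio ≥ 3 at every temperature, which biexponential fitting needs), and
keep $\omega\tau_c \gtrsim 0.15$ even at 90 °C so the $R_2/R_1$ ratio
stays usefully above 1 — below that the ratio route loses sensitivity,
which is a property of the physics, not of the code. The effective $K$
values correspond to effective proton-pair distances of roughly 1.9 and
2.7 Å; the water value is smaller than a rigid-pair estimate because
fast internal motion averages part of the coupling away.

What the simulator does **not** emulate: instrument artifacts (pulse
miscalibration, $B_1$ inhomogeneity), diffusion in field gradients, fat
crystallization, exchange between pools, baseline drift. A pipeline that
recovers the generator's parameters has therefore been shown to work
under the stated statistical model of the measurement — not under every
failure mode of a real spectrometer.

## The Arrhenius stage

`fit_arrhenius()` is ordinary least squares of $\ln\tau_c$ on $1/T$
(at least three distinct temperatures). The reported uncertainty is the
OLS slope standard error scaled by $R$ — published tables of this kind
rarely state whether their ± is an SE, an SD, or replicate spread, so
the package picks the regression SE and says so. Temperatures are kelvin
internally; Celsius is converted at the boundary. Optional weights allow
inverse-variance weighting on the $\ln\tau_c$ scale when upstream
uncertainties are available; by default all temperatures count equally.
Display rounding is half-up to one decimal (the convention of the
published tables); CSV output keeps full precision.

## End-to-end behaviour and problem sizes

The whole chain is validated closed-loop in the test suite and the
acceptance script, at sizes chosen to exercise the statistics while
keeping a full run in seconds-to-a-minute on one core:

* fit recovery on noiseless biexponential traces to relative $10^{-3}$
  over the admissible box ($T \in [10\,\mathrm{ms}, 2\,\mathrm{s}]$,
  fractions in $[0.1, 0.9]$, ratio ≥ 3);
* 100 seeded CPMG replicates at SNR 200 (200 echoes): median relative
  $T_2$ error well under 3%;
* a 10-temperature, 0–90 °C synthetic emulsion: activation energies
  recovered within 2% noiseless and within 10% at SNR 100;
* the ratio inversion checked against an exhaustive
  $10^4$-points-per-decade grid oracle over
  $\tau_c \in [10^{-12}, 10^{-6}]$ s.

## Reference data

Two fixtures ship with the package: gas-chromatography fatty-acid
profiles of the beef and pork fats used as oil phases (the pork profile
sums to ~97.1% because minor acids are unresolved — totals are validated
against a deliberately wide $[95, 101]$ band with a warning, not an
error), and the published per-condition activation-energy table
(2 starches × 3 concentrations × 2 fats × 2 phases). The latter derives
from undeposited raw measurements and is reference data only: nothing in
this package recomputes it, and the simulator presets that mimic its
regimes are labelled approximate. One internal inconsistency in the
source material is preserved rather than reconciled: the prose total for
pork oleic + linoleic (49.0%) disagrees with the profile-table sum
(48.947% → 48.9%); the fixture stores the table values.

## Known limitations

* Single-$\tau_c$ BPP only: no Cole–Cole or Lipari–Szabo spectral
  densities, no cross-relaxation, no chemical exchange. If the real
  system's ratio dispersion deviates from single-$\tau_c$ BPP, the
  extracted $\tau_c$ is an effective value.
* The ratio method degenerates as $\omega\tau_c \to 0$ (ratio → 1):
  high-temperature, low-viscosity points carry little information about
  $\tau_c$, and their noise is amplified. The clamp flags make this
  visible in results.
* T1 and T2 are fitted independently per temperature; a joint fit could
  pool statistical strength but would entangle the two sequences' noise
  models.
* Concentration labels are metadata only; no concentration-dependence
  model is fitted.
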