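---
title: "Quantitative flow NMR, NIR calibration transfer, and economic real-time optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative flow NMR, NIR calibration transfer, and economic real-time optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flownmr)
```

# The monitored process

`flownmr` implements the quality-monitoring and control stack of a
continuous lithiation reactor: aniline and 1-fluoro-2-nitrobenzene
(o-FNB), both dissolved in THF, are coupled by the lithium base LiHMDS
(two equivalents per coupling) into the product lithium
2-nitrodiphenylamine (Li-NDPA), with a lithiated-aniline intermediate
observable only online.  Three sensors and algorithms cooperate:

1. a benchtop 43.32-MHz flow NMR spectrometer sampling every 15 s,
   quantified by Indirect Hard Modeling (IHM) with a one-point absolute
   calibration;
2. an FT-NIR spectrometer sampling every 160 s and sitting 2 min
   downstream, calibrated *against the NMR* by partial least squares
   regression (PLSR) on steady-state-gated reference values;
3. an economic real-time optimizer (modifier adaptation with quadratic
   approximation, MAWQA) that drives the feed flowrates toward the
   plant's profit optimum despite a deliberately crude process model.

Because the pilot plant itself is not available on a desk, the package
ships a first-class virtual plant (`reactor_steady_state()`,
`run_campaign()`) that forward-synthesizes NMR and NIR spectra from
ground-truth compositions, so every algorithm is testable end to end.

# Spectral quantification by Indirect Hard Modeling

At 43 MHz the aromatic multiplets of the three aniline-derived species
collapse into broad, overlapping envelopes; individual peak integrals
are not accessible.  IHM instead fits a *constrained superposition of
pure-component models* to the mixture spectrum.  Each analyte is a sum
of pseudo-Voigt peaks

$$V(x) = h\,[\eta\, G(x) + (1-\eta)\, L(x)],$$

with Gaussian and Lorentzian parts sharing position and FWHM.  When a
pure-component model is built (`fit_pure_component()`), its relative
peak areas are frozen.  The mixture fit (`fit_mixture()`) may only
rescale a component as a whole (one non-negative weight), shift it
globally (±0.05 ppm), shift individual peaks slightly (±0.01 ppm), and
scale its width uniformly (factor 0.8–1.25); a polynomial baseline
(default order 2) is fitted jointly.  Because heights and the common
width scale multiply every peak area equally, the intra-component
area ratios are preserved *exactly* — a hard structural constraint, not
a penalty.  The optimizer is a bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) with an analytic Jacobian; starting weights come
from a linear projection, and up to two deterministically jittered
restarts are tried if the first fit leaves more than 5 % relative
residual.

Concentrations follow from the fitted absolute integrals $A_i$ through

$$c_i = \xi\, A_i/\nu_i,$$

where $\nu_i$ is the number of nuclei behind the modeled signal and
$\xi$ a single conversion factor determined by *one-point calibration*
on the pure o-FNB feed of known concentration (0.63 mol/L), pumped
through the sensors at start-up (`calibrate_xi()`, `quantify()`).

```{r ihm-example}
lib <- default_component_library()
cal <- synth_nmr_spectrum(c(oFNB = 0.63))        # noiseless feed spectrum
fit <- fit_mixture(cal, lib["oFNB"])
xi <- calibrate_xi(fit$areas[["oFNB"]], lib$oFNB$nu, known_conc = 0.63)
xi
quantify(fit, xi, nu_map(lib))
```

The proton counts of the default library are $\nu$ = 5 (aniline
aromatic ring), 4 (o-FNB), 18 (LiHMDS trimethylsilyl singlet), 5
(Li-aniline) and 9 (Li-NDPA); the o-FNB calibration integral uses its
four aromatic protons.  The library peaks are *synthetic but
field-plausible* models (positions, widths and overlap chosen for a
43-MHz instrument), normalized so each component's total area equals
its $\nu$; the model database can be serialized as plain-text configs
(`write_component_model()`).

# FID processing

`process_fid()` zero-fills to 64 k points, apodizes with an exponential
window (0.5 Hz line broadening), Fourier-transforms and converts the
axis to ppm; the scaling is chosen so a unit decay $e^{-\pi d t}$
yields a Lorentzian of height $1/(\pi d)$ and FWHM $d$ Hz.  The complex
spectrum rides along in `meta$complex` so that `auto_phase()` can run
downstream.

Phasing minimizes the squared negative intensity of the real part with
two robustness measures that matter in practice: a noise floor (one
robust SD) so random negative excursions do not bias the objective,
and a gate on the first-order term, which is weakly identified on
noisy spectra with clustered peaks — a $\varphi_1$ is accepted only if
it lowers the penalty decisively (by at least 25 %, above an absolute
floor).  Entropy of the intensity derivative enters at tie-break
weight only.  `baseline_correct()` uses iterative *one-sided* 3σ
clipping (six rounds): absorption signal and its tails lie above the
baseline, so only upward outliers are discarded; the subtracted
polynomial is paired with its Hilbert-transform counterpart so the
complex spectrum stays consistent.  `align_to_reference()` shifts
user-defined ppm intervals by the integer lag maximizing
cross-correlation with a reference spectrum (interval-correlation
shifting), filling gaps with edge values.

The processing order used throughout the package is **phase →
baseline → align**, iterating phase and baseline once more for spectra
that carry a baseline offset: an offset flattens the negative-area
phase objective (first pass lands within a few degrees), and
estimating a polynomial baseline on a badly phased spectrum is
corrupted by dispersion wings — the interleaved passes resolve the
coupling from both sides.

# The virtual plant

`reactor_steady_state()` is a stoichiometric steady-state model.  Molar
feed flows come from mass flows, solution densities (0.90 kg/L,
consistent with the 900 kg/m³ mixture density) and feed concentrations
(0.96 / 1.10 / 0.63 mol/L for aniline / LiHMDS / o-FNB; the start-up
recipe 3.68 / 6.89 / 5.60 kg/h then gives a 2.14 stoichiometric excess
of the base).  The LiHMDS feed is first reduced by a moisture sink
(residual water consumes base), then the reaction extent is

$$\xi_\mathrm{rxn} = \mathrm{smin}(n_\mathrm{an},\, n_\mathrm{oFNB},\,
  n_\mathrm{Li}^\mathrm{eff}/2)\cdot
  m\,\frac{e}{e + k_\mathrm{sat}},\qquad
  e = \frac{n_\mathrm{Li}^\mathrm{eff}}{2\min(n_\mathrm{an}, n_\mathrm{oFNB})},$$

a saturating conversion law with mixing efficiency $m$.  The limiting
term is a log-sum-exp *soft* minimum (relative width 5 %): a hard
`min` would put a non-smooth crease exactly along the economic ascent
valley where the aryl feeds balance, which no real (imperfectly mixed)
reactor exhibits and which defeats any gradient-based optimizer;
`smoothing = 0` restores the hard minimum.  A fixed fraction (0.35) of
the unconverted aniline pool leaves as the lithiated intermediate.
Aryl and fluoroarene mole balances close to 1e-9 by construction.

The *nominal model* uses `plant_params()` (k_sat 0.05, moisture sink
0.3 mol/h, ideal mixing); the *true plant* uses `true_plant_params()`
(0.12, 0.5 mol/h, mixing efficiency 0.92) — parametric *and*
structural mismatch.  A feed-batch change (LiHMDS 1.10 → 1.00 mol/L)
can be scheduled as a disturbance.

`run_campaign()` walks a set-point schedule (default: four 10-min
holds jittered ±12 % around the recipe), relaxes outlet concentrations
first-order with a 120-s time constant, and emits NMR spectra every
15 s and NIR spectra every 160 s with the 2-min inter-sensor delay.
All randomness flows through one seed; identical seeds give identical
bundles.

## The noise budget

The generator's NMR noise default (`nmr_noise_sd = 0.12` intensity
units) is set by a workflow constraint rather than aesthetics: the
steady-state rule (11-point moving fit at 15-s spacing, slope
< 0.1 mol L⁻¹ h⁻¹ *jointly for five analytes*) tolerates a
shot-to-shot concentration repeatability of at most ≈ 2 mmol/L before
its steady yield collapses — the window slope SD is
$\sigma\sqrt{12/(n(n^2-1))}/\Delta t$, about $23\,\sigma$ per hour at
these settings, so $\sigma = 2$ mmol/L already puts half the noise
realizations of a single analyte near the slope bound.  At the
default, single-spectrum quantification
errors are ≈ 1–6 mmol/L per analyte (bias from peak overlap, residual
shift and phase included), at the favorable end of the few-mmol/L
accuracy typical of benchtop flow NMR, and ~85–90 % of settled hold
tails classify steady.  The NIR generator adds analyte-linear Gaussian
bands, SNV-removable multiplicative scatter, and noise amplified
ten-fold in the flanking 12000–8975 and 4611–4000 cm⁻¹ regions, which
mirrors where real spectra are absorption- or detector-noise
dominated.

What the generator does *not* emulate: temperature-dependent chemical
shifts, solvent background (the THF signal is treated as removed),
radiation damping, NIR band nonlinearity at high absorbance, and
drifting instrument response.  Passing tests therefore demonstrate
algorithmic correctness under controlled conditions, not instrument
validation on plant data.

# Steady-state gating and reference pairing

`classify_steady()` applies the printed rule: a centered 11-point OLS
line per analyte; steady iff |slope| < 0.1 mol L⁻¹ h⁻¹ *and* residual
SD < 0.01 mol L⁻¹, for every analyte jointly (whole spectra are
selected, not per-analyte points).  The SD is taken over the fit
residuals — a raw-value SD would double-count the slope.  Window edges
are transient by construction.  `smooth_steady()` replaces steady
points by a trailing 6-point moving average over steady points only
(the centering convention is not dictated by the rule; trailing keeps
it causal).  `pair_references()` compensates the 120-s inter-sensor
delay, matches nearest neighbors (ties to the earlier NMR point,
|gap| ≤ one 15-s interval) and only pairs steady references;
`split_by_run()` partitions by production day, mirroring the
calibration/test split by days.

# NIR calibration transfer by PLSR

Preprocessing follows per-analyte pipelines (`analyte_pipelines()`):
restrict to the quantitatively usable 4611–8957 cm⁻¹ region, then SNV
(sample-SD convention) — in that fixed order — for aniline, Li-NDPA
and Li-aniline; o-FNB instead uses a third-order polynomial baseline
over its 5995–6307 cm⁻¹ band.  Factor counts are 1 / 3 / 5 / 4 for
aniline / o-FNB / Li-NDPA / Li-aniline.  The aniline and Li-aniline
feature windows with secondary baselines are configuration (their
exact plant values live in supplementary instrument tables; the
defaults here match the synthetic band library).  `fit_plsr()` is a
NIPALS PLS1 with mean centering — written in-package because no PLSR
implementation is available in the target environment — and is pinned
in the tests to OLS and pseudo-inverse oracles at the rank limits.
`cross_validate()` offers the 20-random-segment scheme (seeded
Fisher–Yates shuffle, default seed 20171017) and systematic
leave-one-run-out CV; `evaluate_test()` reports RMSE in mmol/L with
parity data.

# Economic real-time optimization (MAWQA)

The profit per hour is

$$\mathrm{Profit} = w_4\, M_\mathrm{Li\text{-}NDPA}\,
  \frac{c_\mathrm{Li\text{-}NDPA}}{\rho_\mathrm{Mixture}}\sum_i u_i
  \;-\; \sum_i w_i u_i,$$

with weights 10 000 / 25 000 / 12 000 / 450 000 kg⁻¹, the product
molar mass 0.2202 kg/mol, mixture density 900 kg/m³, flowrates in
kg/h and the measured product concentration in mol/m³ (the NMR
pipeline's mol/L are converted at the module boundary).  Constraints:
box bounds 0.5–12 kg/h per feed and a LiHMDS:aniline molar feed ratio
≥ 2 evaluated with the configured feed concentrations and densities.

Modifier adaptation corrects the *optimization problem* instead of the
model parameters: at the current point $u_k$ the measured profit
supplies a zeroth-order bias $\varepsilon$ and the difference between
the estimated plant gradient and the model gradient supplies a
first-order modifier $\lambda$; `nominal_optimize()` then maximizes
$\mathrm{profit}_\mathrm{model}(u) + \varepsilon + \lambda^\top(u-u_k)$
inside an ∞-norm trust region.  Plant gradients are never finite
differences of noisy single measurements: `estimate_gradient_quadratic()`
fits a full quadratic surrogate to the operating-point history
(screened for ≥ 10 points, pairwise spacing, design rank and condition
number) and differentiates it — the derivative-free-optimization
element of MAWQA.  When the design is not poised the algorithm
requests probing moves (axis and diagonal steps; probes that would
leave the box are reflected inward so the design stays poised on
active bounds).

Concrete defaults, chosen here because the method's sources specify
the scheme only in outline: probe step 5 % of the start flows, trust
radius 10 % of ‖u₀‖ (shrink ×0.5 on profit regression, grow ×1.3 on
improvement, floor 0.05 kg/h), step tolerance 1e-3 kg/h, and a plateau
rule (four consecutive iterations without measurable progress) as the
practical convergence signal at constrained optima.  Two situations
get special handling.  *Infeasible starts*: the plant is started
sub-stoichiometric (3.58 kg/h each, molar ratio ≈ 1.15 < 2), so when
the ratio boundary is outside the trust region the optimizer takes a
feasibility-restoration step instead of failing; the stoichiometric
constraint is then active (ratio exactly 2) whenever the unconstrained
optimum lies below it.  *Disturbances*: each iteration re-measures the
current point; a persistent profit shift beyond 1 % flushes the stale
history, resets the trust region and re-probes, which is what lets the
optimizer re-converge after the LiHMDS feed-batch change.  The
modified-problem solver is multi-start L-BFGS-B (the stoichiometric
min-terms make the model profit piecewise smooth; a single start can
stall on a kink), with the active-ratio sub-problem solved exactly on
the constraint boundary.

In end-to-end operation the plant measurement is the NMR-quantified
product concentration; `make_response_fn()` exposes a noiseless oracle
mode (used by the deterministic convergence checks) and a noisy mode.

# Numerical choices and problem sizes

* NMR spectra are synthesized on 2048 points over −1 to 11 ppm
  (0.0059 ppm/point, ≈ 8 points per FWHM); campaign quantification
  disables per-peak shifts and warm-starts each fit from the previous
  solution for speed — the global shift absorbs the simulated drift.
* The acceptance-scale studies use 200 random mixtures for the
  quantification error, four 40-min campaign runs (≈ 160 NMR / 14 NIR
  spectra each) for the calibration transfer, and a 51³ profit grid
  (with local polish) as the independent optimum for MAWQA — sizes
  chosen so a complete desk run finishes in a few minutes.
* Dispersion counterparts of synthetic absorption spectra come from an
  FFT-based periodic Hilbert transform; peaks are kept ≥ 1 ppm from
  the axis edges so wrap-around effects are negligible.
* Steady-hold checks judge points whose centered classification window
  lies inside the hold and past ≈ 3 relaxation time constants;
  neighbors of a set-point change are transient by construction of the
  centered window.
* The simulator's dilution effect means the product *concentration* is
  not monotone in the LiHMDS feed (the molar flow is); tests assert
  the flow version.

# Known limitations

* The pure-component library is synthetic; on real spectra the models
  must be rebuilt from measured pure-component spectra
  (`fit_pure_component()`), and instrument-specific constraint bounds
  may differ.
* `auto_phase()` targets absorption-mode spectra with mostly positive
  signal; heavily negative spectra (e.g. edited experiments) are out
  of scope.
* The JCAMP-DX reader covers the AFFN `(X++(Y..Y))` and XY-pair
  dialects only, not vendor compression (SQZ/DIF/DUP).
* MAWQA convergence is a practical plateau criterion, not a global
  guarantee; heavily noise-corrupted profits enlarge the converged
  neighborhood.
* The reactor model is stoichiometry + saturation + delays by design;
  it does not attempt kinetics, heat effects or mixing physics.
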