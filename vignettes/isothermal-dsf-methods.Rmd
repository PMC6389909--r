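---
title: "Isothermal analysis of DSF melt curves: model and methods"
author: "isoDSF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isothermal analysis of DSF melt curves: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoDSF)
```

# The problem

A differential scanning fluorimetry (DSF / ThermoFluor) experiment heats a
protein in the presence of a reporter dye and records fluorescence as the
protein unfolds, one curve per well, across a ladder of ligand
concentrations. A stabilizing ligand shifts each curve's midpoint
$T_m$ upward, but the size of the shift is a convolution of binding
affinity, binding enthalpy, and the unfolding thermodynamics — the shifts
alone do not yield a dissociation constant, and every point of a
$\Delta T_m$ dose series is measured at a *different* temperature, where
the binding constant differs.

`isoDSF` sidesteps this by working at a single temperature. Each melt
curve is fit individually; the fitted curves are evaluated at one slice
temperature $T_s$ near the ligand-free midpoint, producing
$f_u([L]_T)$ — the fraction unfolded versus total ligand — which a simple
coupled-equilibrium model describes with two constants, $K_U$ and $K_d$,
both *at* $T_s$.

# Models

## Per-curve models

Raw fluorescence is modeled as folded/unfolded dye baselines mixed by the
fraction unfolded:
$$Y(T) = (1-f_u(T))\,(m_F T + b_F) + f_u(T)\,(m_U T + b_U).$$
Baselines are linear in the Celsius-scale temperature (the instrument
scale); all thermodynamic expressions use kelvin
($T_K = T_C + 273.15$) and $R = 1.987204\times10^{-3}$ kcal mol⁻¹ K⁻¹,
matching the kcal-based enthalpy units practitioners quote.

Two forms of $f_u(T)$ are available:

* **Boltzmann** (empirical): $f_u = 1/(1+e^{(T_m-T)/a})$, with midpoint
  $T_m$ (°C) and steepness $a$ (°C, $>0$). Used only for midpoint
  determination and normalization; $a$ has no thermodynamic meaning.
* **Thermodynamic** (two-state):
  $\Delta G_U(T) = \Delta H_U(1-T/T_m) - \Delta C_p\!\left(T_m - T + T\ln(T/T_m)\right)$,
  $K_U(T) = e^{-\Delta G_U/RT}$, $f_u = K_U/(1+K_U)$. $\Delta C_p$ is
  almost never identifiable from a single melt curve, so it is **held
  fixed** (user input, kcal mol⁻¹ K⁻¹; 4 is the documented example value
  for an MBP-sized protein — supply a calorimetric or
  buried-surface-area estimate for your protein). By construction
  $\Delta G_U(T_m)=0$, so $K_U(T_m)=1$ and $f_u(T_m)=\tfrac12$ exactly —
  the test suite asserts this identity to machine precision.

Both printed sigmoid conventions in the literature differ in an additive
constant; the forms above are the $0\!\to\!1$ normalization consistent
with reading the signal as a fraction unfolded.

Because the dye's temperature response does not depend on which well it
sits in, `fitGlobal()`/`fitCurves()` can share the two baseline *slopes*
($m_F$, $m_U$) plate-wide while keeping midpoint, enthalpy (or
steepness) and baseline intercepts per-well. Sharing is the pipeline
default; per-well independent fits are available
(`globalSlopes = FALSE`) and are what the curves with genuinely different
slopes require (the joint fit then simply pays a documented residual
penalty, it does not error).

## The isothermal binding model

At the slice temperature the system is
$U + L \rightleftharpoons F + L \rightleftharpoons FL$ with
$K_U=[U]/[F]$ defined on the *unbound* protein and
$K_d = [F][L]/[FL]$ the unbinding constant. Mass balance gives the free
ligand as the nonnegative root of
$$[L]^2 + \big([P]_T - [L]_T + K_d(1+K_U)\big)[L] - [L]_T K_d(1+K_U) = 0$$
and
$$f_u = \frac{1}{1 + (1/K_U)(1 + [L]/K_d)}.$$
The assumptions inherited from this scheme: two-state folding, 1:1
stoichiometry, ligand binds only the folded state (stabilizers only), dye
effects not modeled. Destabilizing ligands, multi-site binding, and
binding to the unfolded state are out of scope.

An exact corollary — no weak-binding approximation involved — links the
dose-response midpoint to the affinity:
$$EC_{50} = \frac{K_d}{1-f_{u0}} + \frac{[P]_T}{2}, \qquad
  f_{u0} = \frac{K_U}{1+K_U},$$
where $EC_{50}$ is the total ligand concentration at which $f_u$ drops to
half its zero-ligand plateau $f_{u0}$. The property suite verifies, over
randomized $(K_d, K_U, [P]_T)$, that evaluating the full model at this
$EC_{50}$ returns exactly $f_{u0}/2$ (to $10^{-10}$), and that species
reconstructed from the free-ligand root satisfy both conservation laws to
$10^{-10}$ relative.

The tight-binding limit is fundamental, not numerical: as
$K_d \to 0$, $EC_{50}\to[P]_T/2$ and the data cease to constrain $K_d$.
Whenever the fitted $EC_{50} \le [P]_T$, `fitIsothermal()` flags the
result and reports the upper bound $K_d < (1-f_{u0})[P]_T/2$ instead of
trusting the point estimate.

# Fitting machinery and numerical choices

* **Optimizer.** All nonlinear fits use Levenberg–Marquardt
  (`minpack.lm::nls.lm`) with `ftol = ptol = 1e-10` and at most 5000
  function evaluations; the convergence flag is stored on every fit
  object. Positivity constraints ($a > 0$, $\Delta H_U > 0$) are box
  bounds; $K_d$ and $K_U$ are fit as $\log_{10}$ values, which enforces
  positivity and equalizes scale across decades.
* **Starting values** are deterministic and data-driven. Curve fits: the
  midpoint starts at the steepest point of the trace (centred first
  derivative of a ~1.5 °C moving-average-smoothed signal — unsmoothed,
  point noise can out-vote the transition), $a$ at 1 °C, $\Delta H_U$ at
  100 kcal/mol, baselines from straight lines through the first/last 15%
  of points. The plate-wide shared-slope fit is seeded from independent
  per-well fits; the joint ~50-parameter problem is markedly less
  forgiving of crude starts than a 6-parameter one. Isothermal fits:
  $K_U$ from the zero-ligand point via $f_{u0}/(1-f_{u0})$, $K_d$ from
  the logistic midpoint through the closed-form relation.
* **Free-ligand root.** Evaluated in closed form with the conjugate
  rearrangement $2c/(b+\sqrt{b^2+4c})$ when $b>0$, avoiding catastrophic
  cancellation at $[L]_T \ll [P]_T + K_d(1+K_U)$; tested against an
  independent polynomial root extraction.
* **Transition detection.** A curve is fit only if its signal range
  exceeds both a user noise floor and five times a robust noise scale
  (median lag-1 difference / $0.6745\sqrt2$); flat traces raise a classed
  error rather than returning a meaningless fit. In plate-wide fits the
  failing well is returned as a `CurveFitFailure` and the others proceed.
* **Normalization.** $(Y - B_F)/(B_U - B_F)$ with the fitted baselines;
  declared degenerate (classed error) if $B_U \le B_F$ anywhere over the
  central half of the transition ($f_u \in [0.25, 0.75]$, i.e.
  $T_m \pm a\ln 3$, with $a_{\mathrm{eff}} = R T_m^2/\Delta H_U$ for the
  thermodynamic model). Normalized *data* are never clipped — residual
  structure is information; only model-predicted $f_u$ values are clamped
  to $[0,1]$.
* **Extrapolation.** Evaluating a fit more than 5 °C (configurable)
  outside its fitted temperature range attaches a warning.
* **Weights.** Replicate slices carry the standard error of the mean;
  the isothermal fit weights by $1/\mathrm{sem}^2$ when all sems are
  positive and finite, otherwise runs unweighted. Parameter standard
  errors come from the residual Jacobian at the optimum
  ($s^2 (J^\top J)^{-1}$, delta method back to the linear scale); no
  bootstrap is run by default.
* **Degenerate inputs.** Two-parameter isothermal fits require ≥ 4
  distinct concentrations and a zero-ligand point (or an external
  `fixKU`); a spread in $f_u$ below `flatTol = 0.02` means the ligand
  does not stabilize the protein at this temperature and raises an
  informative error.

Fixing $K_U$ from the ligand-free curve versus fitting it jointly are
both exposed: the joint fit is the default (it uses all the data and the
zero-ligand point enters with the same weighting rules as every other
point); `fixKU` is the right choice when the ladder lacks a zero-ligand
well or when an independent, better-determined $K_U$ exists. The test
suite checks the two routes agree within their combined uncertainties
when the supplied $K_U$ matches the zero-ligand estimate.

# The simulator

`simSpec()`/`simulateDSF()` generate curve families from two-state
unfolding (Gibbs–Helmholtz, constant $\Delta C_{p,U}$) coupled to 1:1
binding whose temperature dependence follows the integrated
Gibbs–Helmholtz/van't Hoff form with constant $\Delta C_{p,b}$, anchored
at the ligand-free midpoint via
$\Delta G_b(T_m) = R\,T_m \ln K_d^{T_m}$ (association convention):
$$\Delta G_b(T) = \Delta H_b + \Delta C_{p,b}(T - T_m)
  - T\!\left[\frac{\Delta H_b - \Delta G_b(T_m)}{T_m}
  + \Delta C_{p,b}\ln\frac{T}{T_m}\right],\quad
  K_d(T) = e^{\Delta G_b(T)/RT}.$$
Anchoring identities ($K_U(T_m)=1$, $K_d(T_m)=K_d^{T_m}$) and the
two-point van't Hoff limit at $\Delta C_{p,b}=0$ are asserted in the
tests. Crucially, the simulator evaluates $f_u(T, [L]_T)$ through the
*same* equilibrium solver the fitter uses, so generator and analysis
share one oracle and recovery tests probe the inverse problem, not two
divergent model implementations.

Defaults are the package's reference conditions, chosen to resemble
maltose/MBP: $T_m = 50$ °C, $\Delta H_U = 120$ kcal/mol,
$\Delta C_{p,U} = 4$ kcal mol⁻¹ K⁻¹, $\Delta H_b = -10$ kcal/mol,
$\Delta C_{p,b} = -0.5$ kcal mol⁻¹ K⁻¹, $K_d^{T_m} = 1$ µM, 2 µM
protein; temperature grid $T_m \pm 15$ °C in 0.25 °C steps (121 points);
ladder = 0 plus an 11-step two-fold dilution from 500 µM down to
~0.49 µM (12 concentrations, the usual plate-row layout). Noise is
i.i.d. Gaussian on the *normalized* (0–1) signal, all of it driven by one
integer seed; with baseline parameters present the noisy normalized
signal is mapped through the baselines, so raw-style output carries
proportionally scaled noise. With `noiseSigma = 0` output is
bit-identical regardless of seed.

What the simulator does **not** emulate — and therefore what passing
recovery tests do *not* establish about real plates: aggregation and
irreversible unfolding (the common post-transition signal decay in SYPRO
data), dye–protein interaction and dye depletion, folding intermediates,
pipetting error structure (noise is homoscedastic and uncorrelated),
inner-filter or compound autofluorescence artifacts. An optional
truncate-after-maximum preprocessing hook is deliberately left off by
default; aggregation-affected tails should be inspected, not silently
repaired.

# Validation problem sizes

The packaged validation (test suite plus `scripts/acceptance.R`) uses the
reference conditions above: 12 curves × 121 points per recovery run;
noiseless recovery of $(K_d^{T_m}, K_U^{T_m})$ sliced at 50 °C; noise
robustness at $\sigma \in \{0.01, 0.05, 0.1\}$ with 100 seeds per level
(median relative $K_d$ error is required below 5% at $\sigma=0.01$ and
below 20% at $\sigma=0.05$, with degradation at $\sigma=0.1$); the
noise-robustness runs fit wells independently (`globalSlopes = FALSE`),
which is exact for normalized simulated curves and keeps each of the 300
pipeline runs cheap. Noise in these studies enters the normalized melt
curves, not the sliced $f_u$ points directly: slicing a fitted curve
pools the whole 121-point trace, so the effective noise on each $f_u$ is
several-fold smaller than the per-point $\sigma$ — this is the regime the
method is designed for, and noise applied directly to a 12-point slice
is a harsher (and different) experiment.

# Known limitations

* Affinities are only measurable near the protein's $T_m$ (where $f_u$
  is resolved); no van't Hoff extrapolation of $K_d$ to other
  temperatures is provided. Chemical denaturant can shift $T_m$ into the
  range of interest; the analysis itself is unchanged.
* Tight binders ($K_d \ll [P]_T$) yield only upper bounds, by the
  stoichiometric argument above; lowering protein concentration (within
  detection limits) is the experimental remedy.
* The two-state and 1:1 assumptions are structural; multi-domain
  proteins, intermediates, or multi-mode binding violate them silently
  in any implementation of this model — check residuals.
* $\Delta C_{p,U}$ is an input, not an output; a badly wrong value
  biases the thermodynamic fits (the Boltzmann route is a useful
  cross-check, and the suite requires the two extraction routes to agree
  within 0.02 in $f_u$ near the midpoint on simulated data).
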