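---
title: "Modeling phenotypic switching and stress response in sensitive/tolerant cancer co-cultures"
author: "psmsr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling phenotypic switching and stress response in sensitive/tolerant cancer co-cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmsr)
```

## The model

Co-cultures of cisplatin-sensitive (red-labelled) and cisplatin-tolerant
(green-labelled) NSCLC cells show growth dynamics that constant-payoff
ecological models cannot reproduce: the interaction between the two
populations changes over the course of an experiment, and the phenotypes
themselves are plastic. The phenotype switch model with stress response
(PSMSR) explains this with three coupled mechanisms:

* growing sensitive cells (S) generate a hidden, diffusible "stress"
  $C_{str}$; tolerant cells (T) remove it:
  $dC_{str}/dt = K_{str} S - K_{str,d} T$;
* stress suppresses the effective growth rates,
  $K_{GS} = K_{GS0} - a\,C_{str}$ and $K_{GT} = K_{GT0} - b\,C_{str}$
  (effective rates combine proliferation and death and may go negative —
  they are deliberately not clamped);
* the two phenotypes interconvert by first-order switching with equilibrium
  constant $K = K_a/K_b$, and stress shifts the equilibrium toward tolerance:
  $K = K_0 + g\,C_{str}$ with $K_b$ fixed.

The phenotype totals obey

$$\frac{dS}{dt} = -K_a S + K_b T + K_{GS} S, \qquad
  \frac{dT}{dt} = +K_a S - K_b T + K_{GT} T.$$

Cisplatin adds an exposure-dependent death term per phenotype,
$-\mathrm{SCALE}\cdot\mathrm{sigmoid}(AUC)\cdot N$, where
$AUC = \text{concentration} \times \text{exposure time}$ (µM·h) is the drug
memory variable and

$$\mathrm{sigmoid}(AUC) = \left\{1 + \exp\left[\ln 19\left(1 -
  2\,\frac{AUC - AUC_5}{AUC_{95} - AUC_5}\right)\right]\right\}^{-1}$$

equals 0.05 at $AUC_5$ and 0.95 at $AUC_{95}$.

### Lineage resolution

Experimentally, cells are detected by their label (red/green) regardless of
their current phenotype. The package therefore integrates a lineage-resolved
state $(R_s, R_t, G_s, G_t, C_{str}, AUC)$: each label block carries the same
switching/growth/kill structure, and summing the blocks reproduces the
two-variable phenotype-total equations exactly (this identity is tested).
Red cells are seeded 100% sensitive and green cells 100% tolerant, with
$C_{str}(0) = AUC(0) = 0$. This makes the switched-phenotype fractions
$G_s/(G_s+G_t)$ and $R_t/(R_s+R_t)$ directly computable — the quantities
behind the headline model predictions.

## Units and conventions

* Time is in **days**; the fitted rate magnitudes (e.g. $K_{GS0} \approx
  0.71$) are only consistent with the observed roughly eight-fold growth in
  96 h on a per-day scale.
* $AUC$ stays in **µM·h** ($AUC_5 \approx 239 \approx$ 5 µM × 48 h), hence
  $dAUC/dt = 24 \cdot \text{conc}$ with concentration in µM.
* Seeding ratios r:1 follow the **sensitive:tolerant** convention of the
  heterotypic prediction panels (red majority at 8:1); the experimental
  3-week panels are described tolerant:sensitive in places, so the
  convention is an explicit argument (`seedingDesign(..., convention)`).
* After washout the default exposure memory mode is **hold** (the literal
  reading of a memory effect); exponential decay with a stated half-life and
  reset-at-washout are available and every therapy artifact records which
  mode was used.

## Parameters

The four published condition rows (heterotypic immediately after mixing,
heterotypic after three weeks of cohabitation, and both under continuous
5 µM cisplatin) ship as `presetParams()`; `searchRanges()` carries the
published fitting bounds. Two structural facts about the drug rows are
honored everywhere: $K_b = 0$ and $K_{str,d} = 0$ (phenotypic switching and
stress removal are turned off under drug — enforced by the fitting mask of
`fitCondition()`), and the sensitive-growth stress coupling $a$ is unused.
The tabulated $S_{drug}$ constant has no role in the main-text dynamics; it
is stored for config round-trip fidelity and can optionally be coupled as a
drug-on stress source (`sdrugStress = TRUE`), off by default.

### The stress-coupling form

Only monotonicity of the stress couplings is structurally required; the
linear form above is the default. A sigmoidal alternative replaces each
linear map by a saturating tanh with identical value and slope at
$C_{str} = 0$ and amplitude defaulting to the baseline value (so growth
rates saturate at zero instead of going negative). Fits are insensitive to
this choice; predictions at high stress are not — under the linear law the
tolerant fraction of each lineage approaches the stress balance point
$K_{str}/K_{str,d}/(1 + K_{str}/K_{str,d}) \approx 11\%$ for the heterotypic
row, slightly above the published rounded figure-read of ~10%. We keep the
linear default and report the computed value as is.

## Numerical choices

`simulateTrajectory()` integrates with lsoda (stiff-safe; compiled
right-hand side; rtol = atol = 1e-8) and restarts at every dosing-episode
boundary so the piecewise-constant concentration is exact. Stress is a
non-negative quantity: in tolerant-majority cultures the removal term would
otherwise drive $C_{str}$ below zero (and the switch equilibrium with it),
so the stress derivative has a reflecting boundary at $C_{str} = 0$. The fitting
objective uses a package-authored compiled Dormand–Prince 5(4) integrator
that stacks all series of a condition into one call; the two engines agree
to ~1e-9 relative on the study designs and the agreement is tested. Tiny
negative excursions (below 1e-6 cells) are clamped to zero at reporting
time. A readable R implementation of the right-hand side (`psmsrRHS()`) is
exported and tested against the compiled one.

## Fitting

The observation model is lognormal multiplicative error — Gaussian residuals
on log counts — chosen because counts span orders of magnitude and no noise
model is published; the noise SD is profiled out analytically (the fixed-σ
variant is available). A simulated count that is non-positive at an
observation time yields a large finite penalty (1e8), not NaN. Optimization
is a package-authored real-valued GA (binary tournament selection, BLX-0.5
crossover, bounded Gaussian mutation with SD 10% of each range, elitism;
defaults 100×300 at crossover 0.8/mutation 0.1, mirroring common real-valued
GA packages), followed by two rounds of bounded L-BFGS-B polish. All
finite-difference steps and scaling are set per parameter range — the ranges
span five orders of magnitude, so unscaled defaults would silently fail.

Confidence intervals are profile-likelihood based: one parameter is fixed on
an adaptively extended grid, all others re-optimized (warm-started from the
neighboring grid point and, as a second start, from the global optimum), and
the 95% interval is read off where $2\,\Delta\mathrm{NLL}$ crosses the
$\chi^2_1$ 0.95 quantile (3.84). A profile that stays flat is flagged
non-identifiable with the affected side reported at the parameter bound.
The method behind the published intervals is not stated, so no numeric
equality with them is claimed.

Identifiability: the stress scale is internal, so
$(K_{str}, K_{str,d}) \to (\lambda K_{str}, \lambda K_{str,d})$,
$(a, b, g) \to (a, b, g)/\lambda$ leaves the likelihood invariant — single
stress parameters are set-identifiable only. The growth rates $K_{GS0}$ and
$K_{GT0}$ are well identified, which is why the recovery experiment tracks
their CI coverage. Each cohabitation condition is fitted independently with
its own parameter set (the model's premise); a joint fit is deliberately not
provided.

## The synthetic-data generator

`generateDataset()` emulates the live-imaging campaign the analysis assumes:
73 time points (2-hourly over 144 h), seeding ratios 1:1–8:1 at 5000 total
cells, monotypic red/green cultures plus the two heterotypic cohabitation
histories and their continuous-cisplatin counterparts, lognormal noise with
σ = 0.05 by default, counts rounded to 3 decimals so CSV round trips are
byte-exact. The default design yields 2482 records, matching the scale
(~2900) of the original campaign. Ground truth is the published parameter
table; since no monotypic row is printed, the monotypic conditions reuse the
heterotypic row and are labelled accordingly in the metadata. What the
generator does *not* emulate: confluence/carrying-capacity attenuation (the
model has none — growth saturates only via stress), segmentation artifacts,
well-position effects, and replicate-level batch structure. Passing tests on
these data therefore validate the estimation machinery, not the model's
adequacy for any particular real dataset.

The recovery experiment run by the acceptance suite fits 20 seeded
replicates of the drug-free heterotypic panel (584 observations each) with a
GA of 60×100 plus polish and profiles $K_{GS0}$ and $K_{GT0}$ — sizes chosen
to keep a full replicate near half a minute on one core while leaving the
optimizer enough budget that profile CIs are limited by the data, not the
search.

## Time-varying payoffs

`payoffLandscape()` fits the competitive Lotka–Volterra rate model to
central-difference per-capita growth rates of the label channels over moving
windows (default 4-day windows, 12-h stride). The rate model is linear in
its coefficients, so the unconstrained optimum is exact linear least
squares; only when it leaves the admissible box (r ∈ [0,5], Kc ∈ [10,1e7],
α ∈ [−10,10]) does a seeded multi-start bounded refit run. Two regimes
structure the output and are reported per window:

* **Early transient windows** (first ~1–2 days): the green lineage still
  carries its tolerant seeding composition, the channels are not
  proportional, and $\alpha_{12}$ (effect of the tolerant-seeded channel on
  the sensitive-seeded one) is determined: predominantly negative
  (cooperative — tolerant cells relieve the stress limiting sensitive
  growth), with $|\alpha_{12}| \gg |\alpha_{21}|$.
* **Late windows**: switching equilibrates both lineages to the same
  phenotype mix, the channels grow proportionally, and the split of the
  density dependence between N1 and N2 becomes a ridge direction — signs
  are stable but magnitudes are not identified. These windows are flagged
  (per species) and their regression SEs reported.

`windowLengthDiagnostic()` quantifies the window-length trade-off as this
implementation actually measures it: the mean rate residual *grows* from
sub-day to multi-day windows (a constant-payoff model tracks the
stress-driven rate drift worse over longer spans; the single full-length
window mixes the transient and is not directly comparable), while short
windows have ill-determined coefficients (the regression SE of
$\alpha_{12}$ at 12-h windows is an order of magnitude above 4-day
windows). The published account describes
both very short and very long windows as fitting worse; in this
implementation the short-window pathology appears as parameter uncertainty,
not as rate residual, and the two diagnostics should be read together.

## Therapy regimens

`therapySchedules()` encodes untreated, continuous, intermittent-1 (one
2-day pulse) and intermittent-2 (the pulse plus one extra 4-day episode)
protocols. The published protocol fixes the pulse lengths but not every
calendar boundary; the defaults (two-day recovery before the second episode
on days 4–8, eight-day horizon containing all episodes) are documented
approximations and fully configurable. Past the horizon the untreated arm's
tolerant channel is numerically extinct (see below), which is why the
default horizon ends with the last episode. At the
published drug-row parameters the final tolerant:sensitive label ratio
orders continuous ≥ intermittent-2 ≥ intermittent-1 ≥ untreated (tested),
reproducing the published comparison qualitatively — as the original account
itself claims only qualitative agreement, absolute magnitudes being
distorted by the absence of a confluence term. With stress removal off
($K_{str,d}=0$) untreated populations accumulate stress without bound over
long horizons, so the untreated arm's tolerant channel collapses — ratios
are reported as Inf/NA when a denominator channel goes extinct, and an
optional passaging event (instantaneous 1:5 rescale) exists for long
protocols but is off by default because the model has no confluence term.

## Known limitations

* No spatial structure, confluence or explicit pharmacokinetics; the AUC
  bookkeeping is the only drug memory.
* The exact functional forms of the published stress couplings beyond
  monotonicity, and the published CI method, are appendix-only; this
  package documents its own choices instead of claiming equality.
* Payoff magnitudes in near-proportional windows lie on an identifiability
  ridge (flagged); only their signs and the relative magnitude
  $|\alpha_{12}| > |\alpha_{21}|$ are robust findings.
* Fitted parameter values from the published table come from undeposited
  experimental data; nothing here re-estimates them from real data.
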