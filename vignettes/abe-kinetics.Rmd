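---
title: "An NADH-modulated kinetic model of ABE batch fermentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An NADH-modulated kinetic model of ABE batch fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abekin)
library(dplyr)
```

## The process and the model

Solventogenic *Clostridium* species ferment sugars in two metabolic phases.
During acidogenesis the culture grows and excretes acetic and butyric acid;
as acids accumulate the metabolism shifts to solventogenesis, in which acids
are re-assimilated and acetone, butanol and ethanol (ABE, classically 3:6:1)
are produced. Butanol formation is a sink for reducing power: the route from
acetoacetyl-CoA to butanol spends four NADH per molecule, while glycolysis
regenerates only two NADH per glucose. The availability of NADH therefore
partitions flux between the acid-recycling "cold channel" (CoA transfer to
acetoacetate, decarboxylation to acetone) and the direct "hot channel"
(acetyl-CoA &rarr; acetoacetyl-CoA &rarr; butyryl-CoA &rarr; butanol).

`abekin` implements a structured kinetic model that makes this redox
coupling explicit. Sixteen species (glucose and glycolytic intermediates,
the CoA pool, biomass, acids, solvents and NADH; see `abe_species()`) are
balanced over nineteen reactions:

$$\frac{d\mathbf{C}}{dt} = \mathbf{N}\, \mathbf{r}(\mathbf{C})\, X$$

with $\mathbf{N}$ the 16 x 19 stoichiometric matrix
(`abe_stoichiometry()`), $\mathbf{r}$ the vector of specific rates (h^-1,
per unit biomass, `compute_rates()`) and $X$ the biomass concentration. All
concentrations, including biomass, are in mM.

The rate laws fall into four families:

* **Michaelis-Menten** (`mm_rate()`) for the single-substrate steps
  r2-r7, r9, r10, r16 and r18;
* **dual Michaelis-Menten** (`dual_mm_rate()`), a product of two
  saturation factors, for the CoA-transferase re-assimilation of acetate
  (r8) and butyrate (r15), whose two substrates act independently;
* **ping-pong bi-bi** (`ping_pong_rate()`) for the NADH-coupled
  reductions: ethanol formation (r11), the acetoacetyl-CoA to butyryl-CoA
  reduction (r14) and, with competitive butanol inhibition
  (`ping_pong_inhibited_rate()`), butanol formation (r19). NADH enters these
  laws as a co-substrate, so solvent fluxes stall when the cell runs out of
  reducing power -- no switching functions are needed to reproduce the phase
  transition;
* **bespoke inhibited forms** for glucose uptake (r1: saturable uptake
  with substrate inhibition and butanol inhibition,
  `glucose_uptake_rate()`), growth on acetyl-CoA with butanol inhibition
  (r12), butyrate re-uptake (r17) and a constant specific death rate (r13).

## Transcription decisions

Two places in the published model admit more than one reading; the package
fixes them as follows and keeps each behind a single function or constant so
a revision would be local.

**Stoichiometric coefficients.** The published balance statements -- one
glucose yields two glycolytic NADH, one butanol consumes four NADH, and up
to one butanol is formed per glucose through the hot channel -- jointly pin
the non-unit coefficients: the hexose-to-triose step produces two
glyceraldehyde-3-phosphate (r2), the thiolase condensation consumes two
acetyl-CoA (r10), and each of the three reductions r11, r14, r19 spends two
NADH (each lumps two NADH-dependent dehydrogenase steps). The NADH row
credits only the glycolytic oxidation step (r3); the ferredoxin route from
pyruvate could in principle supply further NADH, but part of that flux is
diverted to NADPH and the balance treats it as net-neutral. We verified
numerically that this bookkeeping -- and none of the all-unit or
ferredoxin-crediting alternatives -- reproduces the published butanol
plateaus and production ceilings.

**Glucose-uptake grouping.** The three constants of r1 are paired as

$$r_1 = \frac{V_1\,[G]}{k_{1A}\left(1 + [G]/k_{1C}\right) +
  [G]\left(1 + [BuOH]/k_{1B}\right)}$$

i.e. the small constant ($k_{1C}$ = 2.56 mM in fit A) drives substrate
inhibition and the large one ($k_{1B}$ = 89.5 mM) butanol inhibition. The
alternative assignment would make 2.56 mM a butanol inhibition constant --
an implausible toxicity threshold given that the model's other butanol
constants are 105.5 and 144.6 mM and cultures routinely exceed 40 mM butanol
-- and would remove the strong high-glucose saturation the response surfaces
show. A Haldane ($[G]^2$) reading was also examined and suppresses
high-glucose conversion entirely. The grouping lives only in
`glucose_uptake_rate()`.

Within the ping-pong family the constants are passed in the per-reaction
printed arrangement: for r11/r14 the `kA` column multiplies NADH and `kB`
the carbon substrate, for r19 `kA` multiplies butyryl-CoA. The family
function itself always uses $K_1 S_1 + K_2 S_2 + S_1 S_2$, so the
inhibitor-free reduction identity holds exactly.

## Parameters and packaged fixtures

`abe_fit("A")` and `abe_fit("B")` return the two published calibrations
(fit A: batch culture of *C. saccharoperbutylacetonicum* N1-4 on 70.6 mM
glucose with 40 mM exogenous acetate; fit B: *C. acetobutylicum* on
277.78 mM glucose). Empty table cells are stored as `NA` -- absent by
omission, never zero-filled. Two quirks are preserved deliberately: fit A
lists a third constant (2.56 mM) for r16 and r18 whose rate laws use only
two constants (stored, never evaluated, flagged once per session), and the
fit B column prints no maximum rate for r16/r18, so simulating fit B
requires supplying `V16`/`V18` via `set_params()`.

`abe_initial("shinto")` is the published batch start (glucose 70.6, biomass
0.20, acetate 40.12, butyrate 2.12, acetone 2.58, butanol 4.46 mM). Species
without a published initial value default to a 10^-3 mM trace; initial NADH
defaults to 2 mM, the middle of the reported physiological range
(0.039-8.49 mM). Both are design choices -- the source states neither -- and
both are plain arguments of `abe_state()`. The Al-Shorgani fixture publishes
only glucose; the remaining entries take the same defaults and the fixture
is documented as partly synthetic.

## Simulation

`simulate_batch()` integrates the system with a stiff multi-step solver
(`deSolve::ode`, lsoda, which switches to BDF where needed) behind a
compiled right-hand side; a pure-R reference (`abe_rhs()`) is exported and
the two are asserted to agree. Defaults: 60 h horizon (the published
fermentation end), 201 reporting points, rtol 1e-8 and atol 1e-10 mM --
tight because the saturation constants span 4e-4 mM to ~500 mM. Stiff
solvers may step transiently below zero; rates are evaluated on the
clamped-at-zero state (keeping the vector field smooth and exact for
admissible states) and reported concentrations clamp negatives above
-1e-6 mM to zero. Halving both tolerances moves no reported concentration
by more than 0.1% relative (tested). `states_at()` interpolates linearly on
the reporting grid, which preserves monotonicity.

## Estimation

`fit_parameters()` solves the weighted least-squares problem
$\min_\theta \tfrac12 \sum_t e(t)^\top W e(t)$, $e_i(t)$ the
predicted-minus-measured concentration, subject to box bounds. $W$ is
diagonal and constant over time, $w_i = 1/\max_t |C_i^{meas}(t)|^2$
(`scaling_weights()`), which is the minimal reading of "equalise the order
of magnitude" across species. Missing cells are skipped, never imputed.

The optimizer is bounded Levenberg-Marquardt (`minpack.lm::nls.lm`) on the
weighted residual vector, with optional seeded log-uniform multi-start. One
numerical choice matters: the finite-difference Jacobian step is set via
`epsfcn = 1e-6` (about 10^-3 relative steps) so that residual differences
stand clear of the integrator's own noise floor at rtol 1e-8; with the
library default the Jacobian is dominated by solver noise and the search
stalls at its starting point. A simulation failure inside the objective
returns a large flat penalty instead of an error. Default bounds are two
orders of magnitude around the starting values.

Identifiability is asserted only for the three rates the sensitivity
analysis singles out ({V1, V10, V14}): on noise-free self-generated data
they are recovered within 5% from 1.5x-perturbed starts, and within 20%
under 5% multiplicative noise across ten seeded replicates (tested). No
claim is made for the full 47-parameter set. Goodness of fit is summarised
per species by the Pearson correlation between prediction and measurement
(`pearson_by_species()`), reported as `NA` for constant measurements.

## Sensitivity analysis

`local_sensitivity()` implements the finite-perturbation relative
sensitivity $S_{i,\theta_j}(\tau) = [C_i(\theta^*,\tau) -
C_i(\theta,\tau)]/C_i(\theta,\tau)$, perturbing exactly one parameter by a
signed fraction and re-simulating; it errors when the base concentration at
$\tau$ is zero (the measure is undefined there). Percentages are $100 S$.
Because the published convention (+&Delta;, -&Delta;, or an aggregate) is
unstated, both signs are computed and `sensitivity_ranking()` ranks by
$\max(|S(+f)|, |S(-f)|)$, breaking ties alphabetically -- deterministic and
order-invariant. The default evaluation times 5, 15 and 60 h mark the
acidogenic phase, the solventogenic phase and the end of the process. For
fractions &rarr; 0, $S/f$ converges to the local elasticity; the test suite
checks agreement within 5% of a central finite difference at $f = 10^{-3}$.

## Scenario sweeps

`run_sweep()` maps endpoint butanol, acetone and their ratio (the
butanol/acetone selectivity, `selectivity()`, undefined below 10^-6 mM
acetone) over grids of initial glucose, NADH and acetate. NADH is applied
as an *initial condition* -- it is a balanced state of the model -- but
`clamp_nadh = TRUE` holds it constant instead, covering the alternative
reading of an externally imposed redox level (e.g. electro-fermentation).
Production is reported at the 60 h endpoint by default; `endpoint = "peak"`
reports each solvent's maximum over time. Failed cells are flagged and the
sweep continues. `locate_extremum()` breaks ties towards the lowest axis
values in axis order (glucose, NADH, acetate).

The analysis-scale grids used by the tests and the acceptance script are
glucose 0-250 mM in steps of 5 and NADH 0-80 mM in steps of 2.5 (1,683
cells) for the selectivity surface, NADH steps of 1 mM for the plateau
scans, and glucose up to 300 mM for the ceilings -- fine enough that halving
any step moves the located extrema by well under the comparison tolerances.

## The synthetic-data generator

`generate_synthetic_dataset()` emulates the statistical shape of the batch
time courses the model is calibrated against: 13 offline samples over
0-60 h of the six routinely assayed species (glucose, biomass, acetate,
butyrate, acetone, butanol), with multiplicative noise of a configurable
coefficient of variation plus an optional additive floor, clamped at zero,
under a mandatory recorded seed. It does *not* emulate systematic assay
bias, autocorrelated drift, missing-at-random gaps, biological replicate
variability, or pH/gas dynamics (which the model itself excludes). Passing
the estimation tests on such data therefore demonstrates correctness of the
fitting machinery and practical identifiability of the targeted subset --
not that the model would calibrate equally well against arbitrary real
cultures.

## Known limitations

* The model excludes pH dynamics, hydrogen production, gas stripping and
  continuous-culture terms by construction.
* Fit B cannot be simulated as published (missing r16/r18 maximum rates).
* Residual transcription ambiguity remains: with the bookkeeping above the
  simulated batch consumes glucose within ~13 h, i.e. faster than the
  published solventogenic time marks suggest, and the low-NADH
  acetone/butanol balance sits below the published selectivity floor. The
  acceptance script recomputes exactly these quantities so the agreement --
  and the disagreement -- is measured, not asserted; the alternatives we
  tested (unit stoichiometry, ferredoxin NADH credits, other r1 groupings)
  disagree more broadly.
* Sensitivities are finite-perturbation measures; they are not the
  derivative-based sensitivities of an adjoint/forward analysis, though the
  small-fraction limit matches a central difference by construction.
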