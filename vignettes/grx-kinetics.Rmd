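---
title: "Modelling glutaredoxin deglutathionylation kinetics with grxkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glutaredoxin deglutathionylation kinetics with grxkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grxkin)
```

## The biochemical system and its model

Glutaredoxins (Grx) reverse protein glutathionylation: they reduce the
mixed disulphide between a protein thiol and glutathione (PSSG),
releasing the reduced protein (PSH), and are themselves re-reduced by
glutathione (GSH). Glutathione reductase (GR) closes the cycle at the
expense of NADPH. Two catalytic mechanisms are commonly drawn — a
*dithiol* cycle through the intramolecular disulphide GrxSS and a
*monothiol* cycle through the mixed disulphide GrxSSG — but once the
shared intermediates and side-reactions are written out the two schemes
have identical stoichiometric structure, so a lumped dithiol
representation suffices for systems-level modelling. grxkin therefore
never represents the transient Grx–SSG–SH intermediate as a species: it
is known to collapse rapidly to GrxSS and would only add an
unidentifiable fast timescale.

All models are mass-action networks in micromolar and seconds. Four
builders cover the cases of interest:

* `build_wildtype_core()` — two reactions over the couple
  Grx(SH)₂/GrxSS, with `v1 = k1·PSSG·GrxSH2` and
  `v2 = k2·GrxSS·GSH²` (the squared GSH dependence is the kinetic
  signature of reduction by two glutathiones). PSSG and GSH are clamped;
  the glutaredoxin moiety is conserved.
* `build_mutant_core()` — the active-site mutant cycles through GrxSSG
  and is reduced by a *single* GSH: `v2 = k2'·GrxSSG·GSH`. Note the
  units: `k2` is µM⁻²s⁻¹ while `k2'` is µM⁻¹s⁻¹; the two constants are
  deliberately separate, unit-tagged fields of `grx_params()` so they
  can never be interchanged or compared directly.
* `build_ecoli_system()` — GR (generic irreversible two-substrate law)
  plus Grx reduction plus deglutathionylation of a clamped peptide
  substrate, optionally with a reversible deglutathionylation step
  (net rate `k1·(GrxSH2·PSSG − GrxSS·PSH·GSH/Keq)`, `Keq` in µM).
* `build_hed_assay()` — the standard activity assay: HED
  (β-hydroxyethyl disulphide) reduction coupled to NADPH consumption
  through GR, at the packaged assay concentrations
  (`grx_profile("grx1")` / `"grx2"`).

### Key closed forms

Setting `v1 = v2` under the moiety constraint gives exact steady-state
laws, implemented in the `v_wt()`/`v_mut()` family:

$$v_{wt} = \frac{Grx_{tot}}{\dfrac{1}{k_2\,GSH^2} + \dfrac{1}{k_1\,PSSG}},
\qquad
v_{mu} = \frac{Grx_{tot}}{\dfrac{1}{k_2'\,GSH} + \dfrac{1}{k_1\,PSSG}}.$$

Three consequences structure the analysis layer. First, in reciprocal
form the wild-type law is linear in `1/PSSG` with slope
`1/(Grx_tot·k1)` — independent of GSH — so families of reciprocal lines
at different glutathione levels are *parallel* (the apparent ping-pong
pattern), while the dependence on `1/GSH` is quadratic, hence curved
(`reciprocal_coefficients()`). Second, at fixed substrate the laws are
algebraically Hill curves in GSH with exponents 2 (wild type) and 1
(mutant) (`hill_form_wt()`, `hill_form_mut()`); the exponent of two
reflects the stoichiometry of GSH oxidation, not binding cooperativity.
Third, the wild-type/mutant rate ratio tends to `k2·GSH/k2'` at
saturating substrate (`rate_ratio_limit()`), which rationalises why a
mutant can out-run its wild type at low GSH yet fall behind as GSH
rises. The saturation condition is implemented as
`k1·PSSG ≫ k2·GSH²` and `≫ k2'·GSH` — the regime in which GSH oxidation
is rate-limiting — which makes dimensional sense of the informal
"large `k1·PSSG`" criterion.

## Numerical choices

**Steady-state solving.** Moiety-closed mass-action networks have
rank-deficient stoichiometry, so the solver first eliminates one species
per conserved moiety through its conservation total, then runs a damped
Newton iteration (finite-difference Jacobian, step-halving line search,
positivity preserved by step shrinking) on the remaining free species.
If Newton stalls it falls back to stiff relaxation
(`deSolve::lsoda`) over geometrically growing horizons and retries. A
state is accepted when `max |d[x]/dt| < atol` (default 10⁻¹⁰ µM s⁻¹),
relaxed by the double-precision rounding floor of the derivative
evaluation, estimated from the Jacobian and state magnitudes: for
parameter draws with very fast fluxes, cancellation between opposing
terms makes a smaller residual unrepresentable, while the implied
*concentration* error stays at relative machine precision. The
`converged` flag is honest — non-convergence is reported, never papered
over — and all reported concentrations are non-negative. The assay model
mixes constants spanning nine orders of magnitude (GR kcat 900 s⁻¹
against k₂ ≈ 4×10⁻⁶ µM⁻²s⁻¹), which is why the integrator contract is
stiff-capable throughout.

**Clamping policy.** NADPH/NADP are always clamped (the assay holds them
via excess substrate); reciprocal-plot protocols clamp GSH and PSSG per
curve, and PSH is always clamped in the coupled system (it is a pure
product in the irreversible variant and would otherwise grow without
bound; the reversible variant requires it for the reverse rate, default
1 µM). In the closed HED-assay model glutathione cycles through GR and
`GSH + 2·GSSG` is registered as a second conserved moiety. The
deglutathionylation stoichiometry keeps its GSH release even when GSH is
clamped (a no-op that preserves exact bookkeeping); because that release
draws on the *clamped* substrate pool, no glutathione moiety is
registered when GSH is left dynamic in the coupled system.

**Rate-law conventions.** The GR law is the separable generic
irreversible two-substrate form
`v = kcat·E·(a·b)/((1+a)(1+b))`, `a = NADPH/K_NADPH`,
`b = GSSG/K_GSSG`, which reduces to Michaelis–Menten in each substrate
and saturates at `kcat·E`. HED is modelled as the glutathionylated
substrate of a single lumped reaction `GrxSH2 + HED → GrxSS` — the
spontaneous HED + GSH pre-reaction is not resolved, matching the
two-constant description the assay supports; the lumped step is net
glutathione-neutral. Zero substrate concentrations are legal everywhere
and produce the continuous limit rate 0 (grids may include the origin;
the reciprocal transform separately drops non-positive points and
reports the count), while zero or negative rate constants and a zero
glutaredoxin total are rejected at construction.

## Plot-level analyses

`to_reciprocal()` and `classify_line_family()` quantify what is usually
read off a Lineweaver–Burk plot by eye. Lines are fitted by unweighted
OLS on the transformed points — the classical reading, kept deliberately
even though weighted fits are statistically superior (a weighted option
exists) — and a family is called **parallel** when the maximal relative
slope spread is below 5%, **converging** when it exceeds 5% *and* the
slopes are strictly monotone in GSH, otherwise **neither**. The 5%
threshold sits an order of magnitude above the analytic noise floor and
is robust under the default 5% assay noise with triplicates; it is a
package convention, since a visual classification has no intrinsic
number. The classification is invariant to dataset order and to uniform
rescaling of the rates.

`fit_hill()` fits `V·σⁿ/(1+σⁿ)` on *untransformed* rates (no Hill
linearisation, avoiding transform bias), by Levenberg–Marquardt on
log-scale parameters (positivity by construction), initialised at the
maximal observed rate, the interpolated half-maximal abscissa and
`n = 1`. A half-saturation estimate outside the data range is recorded
as a warning in the result metadata rather than an error, and
non-convergence flags the result instead of throwing.

## Fitting rate constants

`fit_rate_constants()` reproduces the standard fitting procedure for
assay data: for every trial parameter vector the *entire* reaction
system is re-solved to steady state at each dataset abscissa (no
analytic shortcut — the procedure generalises unchanged to the
GR-coupled assay model), and the Levenberg–Marquardt algorithm
(`minpack.lm::nls.lm`) minimises the squared rate residuals. Parameters
are optimised on the log scale; steady-state failures at pathological
trial points incur a large penalty residual rather than aborting.
Residuals are unweighted by default, with optional `1/sd` weighting when
the dataset carries standard deviations. Standard errors are asymptotic
(delta method from the log scale) and reported only when the residual
Jacobian is full rank; `r² = 1 − SS_res/SS_tot`. Default initialisation
is a crude 5-per-parameter log-spaced grid search spanning one decade
either side of the template values.

## Synthetic data: what it emulates and what it does not

The reference HED-assay datasets behind the packaged Grx1/Grx2 constants
are not publicly deposited, so `generate_hed_dataset()` stands in for
them: true steady-state rates from the assay model over a 10–500 µM HED
grid (15 log-spaced points by default, spanning the 70 µM reference
concentration), multiplied by `(1 + ε)`, `ε ~ N(0, cv²)` truncated at
−0.99 (truncations are counted in the metadata). Constant-CV
multiplicative noise is the natural first model for
spectrophotometric initial-rate assays, where scatter scales with
signal; the default `cv = 0.05` is a typical well-run-assay figure. A
seed is mandatory — generators are pure functions of settings and seed.
Generated datasets carry their known noise SDs, and
`recovery_experiment()` fits with `1/sd` weights: under multiplicative
noise, unweighted least squares gives miscalibrated asymptotic
confidence intervals, so the weighted fit is the correct harness for
coverage assessment.

What passing recovery tests shows is that the estimation machinery is
unbiased and calibrated *under this error model and grid*. Real assay
data additionally carry baseline drift, non-enzymatic background rates,
pipetting-level replicate correlation and possible model misspecification
at the extremes of the HED range (the lumped irreversible HED step is
known to fit worst at the lowest and highest HED concentrations) — none
of which the generator emulates. Recovering the *published* constants
from the original data would require those datasets themselves.

## Problem sizes and defaults used by the packaged analyses

The shipped analyses use: 17-point GSH grids spanning two decades either
side of the half-saturation constant for Hill fits; 15-point log-spaced
PSSG grids over 0.1–20 µM at GSH 150/250/1000 µM for line families (the
number of substrate points per curve is a package default, chosen as
ample for a 2-parameter line); 100 random log-uniform draws over four
decades for the analytic-vs-numerical cross-checks; and 100 seeds at 5%
noise with 20-point grids for the Monte-Carlo recovery study. These
sizes give Monte-Carlo standard errors comfortably below the effect
sizes of interest (e.g. ±2.2 percentage points on a 95% coverage
estimate) while keeping any single analysis in the seconds-to-a-minute
range on one core.

The coupled-system defaults (`ecoli_default_params()`: k₁ 0.1 µM⁻¹s⁻¹,
k₂ 4.23×10⁻⁶ µM⁻²s⁻¹, Grx_tot 1 µM, Keq 1 µM) are representative
magnitudes, not literature constants — the analyses built on that model
are deliberately pattern-level (linearity, parallel versus converging),
never value-level.

## Known limitations

* Only the deglutathionylation step has a reversible form; the package
  makes no claim of full thermodynamic consistency.
* No stochastic simulation, event handling or bifurcation analysis; the
  solver targets steady states and smooth relaxations.
* Hill and line-family classification are geometric criteria; no formal
  model-discrimination statistics (e.g. AIC between ping-pong and
  sequential fits) are computed.
* SBML export is one-way (Level 3 with explicit MathML kinetic laws);
  import and round-trip validation are out of scope.
* The fitting layer is frequentist and single-dataset: no Bayesian
  posteriors, profile likelihoods or multi-dataset global fits.
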