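---
title: "Methods: the IL-27 tumor-immune model, its estimators and its sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the IL-27 tumor-immune model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(il27sim)
```

# The biological network and its mathematical form

The package models the interaction of a growing plasmacytoma-like tumor
with tumor-antigen-specific CD8⁺ T cells (CTLs) under the influence of
IL-27.  The network has five nodes.  Tumor cells present antigen that
activates CTLs.  Activated CTLs secrete two anti-tumor cytokines: IL-10
(in this experimental setting pro-inflammatory and tumor-rejecting) and
IFN-γ.  IL-27 — secreted by gene-transfected tumor cells or injected as a
drug — acts on CTLs three ways: it prolongs their survival, it amplifies
their IL-10 secretion, and it suppresses their per-cell IFN-γ secretion.
IL-10 also prolongs CTL survival, more weakly.

Each interaction is either linear mass action (per-cell production,
first-order degradation, logistic proliferation with death) or a
Michaelis–Menten saturation with a single half-saturation constant — the
simplest monotone bounded response, and the form that matches one constant
per modulated interaction in the parameter table.  The two survival
signals share one denominator, `d_E E / (1 + I27/K_E1 + I10/K_E2)`: the
death rate is divided by a linear combination of the survival cytokines,
so either cytokine alone can at most slow death, never create cells.  The
tumor is spherical and all fields radially symmetric; diffusivities are
spatially uniform.  Full equations are in `?reaction_rates` and the
README.

Model states and assumptions worth making explicit:

* "CD8⁺ T cells" stands for the joint effector compartment.  In the
  wild-type (injection) setting CD4⁺ T cells also respond to IL-27; their
  IL-10 is assumed to act like CTL IL-10, and a single effector density
  represents both populations.
* Killing terms only remove tumor cells; there is no immune exhaustion,
  no angiogenesis, no Treg/macrophage compartment, no delay terms and no
  stochastic kinetics.
* Wild-type tumor cells secrete no IL-27 (`mu1 = 0`); the knockout CTL
  genotype secretes no IL-10 (`lam1 = lam2 = 0`).  These masks are applied
  by `apply_genotype()` exactly as in the four experimental arms.

# Parameters, units and the baseline

Units are days, cm, pg/cm³ for cytokines and cells/cm³ for cell
densities.  The 26 parameters, their units and defaults are listed by
`print(il27_parameters())`.  The baseline is the package's own
self-consistent parameterization, chosen once, by the following
reasoning, and used unchanged by every test and script:

* **Diffusivities.** Cytokines: `8.64e-2` cm²/day (≈ 1e-6 cm²/s, typical
  for ~50 kDa proteins in tissue).  Cell dispersion is taken two orders
  (CTLs) and four orders (tumor) smaller: motile lymphocytes still move
  far less freely than solutes, and plasmacytoma spreads locally.
* **Tumor kinetics.** `lamT = 0.69`/day with `d_T = ln 2 / 2`/day (cell
  half-life 2 days) gives a net exponential growth of `0.343`/day —
  a volume doubling every two days, aggressive but typical of the mouse
  tumors modeled.  Carrying capacity `T_max = 1e9` cells/cm³ (packed
  tissue).
* **CTL kinetics.** `d_E = 1.4`/day: activated effectors contract with a
  half-life of ~12 h when deprived of survival signals, consistent with
  the transfer experiments in which only a few percent of injected CTLs
  remain after four days without IL-27 support.  With survival factors at
  their baseline IL-27 exposure the effective half-life extends several
  fold.  `lamE = 5.8e5` cells/cm³/day and `K_T = 1e7` cells/cm³ make
  activation saturate at low tumor density: antigen is in excess long
  before the tumor approaches capacity.  The low `K_T` matters
  qualitatively — with activation proportional to tumor burden, a
  successful treatment would starve its own effector supply and CD8⁺
  counts would *fall* with treatment, contradicting the experiments.
* **Cytokine production and killing.** `lam2/lam1 = 12.5`: IL-27
  amplifies per-cell IL-10 production by an order of magnitude, the
  central experimental observation.  The kill half-saturations sit inside
  the concentration ranges the model actually produces (`K_kill10 = 25`
  pg/cm³ against ambient IL-10 of a few pg/cm³ and treated levels of
  tens to hundreds; `K_killG = 400` pg/cm³ against IFN-γ of order
  10²–10³), so both kill terms operate on the responsive part of their
  saturation curves.  `K_I27_G = 1e4` pg/cm³ makes IFN-γ inhibition
  partial at tissue IL-27 levels: per-cell production drops, but the
  survival-driven expansion of the CTL pool can still raise total IFN-γ.
* Two degradation rates (`d_I27 = 1.38889`, `d_G = 1.404`/day) adopt
  IL-12-family literature magnitudes; IL-10 turns over faster
  (`d_I10 = 9`/day).

`nondimensionalize()` maps any parameter set to dimensionless form given a
`scale_set()`; the default scales (1 day, the domain radius, `T_max` for
cell densities, each cytokine's principal half-saturation) leave all
first-order /day rates numerically unchanged, which is why the baseline
table reads the same in both forms for those rows.  The round trip with
`dimensionalize()` is exact to 1e-12 by construction and by test.

# The solver

`simulate()` uses the method of lines.  Space is discretized by
conservative finite volumes on `N + 1` uniformly spaced nodes: node *i*
owns the shell between faces `r_i ± h/2`, fluxes are evaluated on faces,
and the zero-flux faces at `r = 0` (zero area, by symmetry) and `r = R`
make diffusion conserve each species' total amount exactly — the
telescoping sum is an identity of the scheme, not an approximation, so
the conservation test can demand 1e-10 over 15 days.  The same dual-cell
volumes define the quadrature in `total_amount()`, keeping transport and
reporting consistent.  No special treatment of the coordinate
singularity at the origin is needed because the origin face carries zero
area.  The scheme reproduces the spherical Laplacian of quadratics
exactly and converges at second order on a manufactured
Neumann-eigenmode solution (tested over `N ∈ {50, 100, 200}`).

Time integration uses the banded-Jacobian stiff path of
`deSolve::ode.1D` (lsoda) on species-scaled variables (each species
divided by a reference scale, so the absolute tolerance is
dimensionless).  Defaults `rtol = 1e-6`, `atol = 1e-9`; tests that
compare against closed forms tighten these.  Output fields are floored
at zero after verifying that no value undershot below the positivity
tolerance (default 1e-6 in scaled units); a worse undershoot is an
error, not a warning.  When an injection protocol switches on or off,
integration is split at the switch times so the integrator never steps
across a source discontinuity.

Initial conditions: the tumor starts as a smooth compactly supported
bump `T0 (1 - (r/ε)²)²` at the origin; CTLs and their cytokines start at
zero; a transfected tumor starts with IL-27 at its quasi-steady ratio
`mu1/d_I27 · T(r,0)`.  Defaults `ε = R/2`, `T0 = 3e8` cells/cm³ put the
tumor in the inner half of a `R = 0.5` cm domain — large enough that
cytokines produced in the tumor are not simply diluted into empty
tissue, small enough that the boundary stays tumor-free (a run warns if
tumor density at `r = R` ever exceeds `1e-6 · T_max`).  Halving ε
changes totals quantitatively but not the treatment ordering (tested).

# Injection protocols

The therapeutic source is `f(r,t) = q(t) exp(-γ (R - r))`: delivery is
strongest at the outer boundary and attenuates toward the core, the
simplest strictly monotone positive profile consistent with drug
arriving from the surrounding tissue.  γ defaults to 1/cm and is
configurable; the comparison conclusions are not sensitive to it.  The
continuous strategy delivers `q1` throughout an 18-week treatment window;
the intermittent strategy delivers `2·q1` for three weeks, pauses three
weeks, and repeats — the amplitude factor 2 is stored explicitly so that
the cumulative dose matches the continuous arm at every radius over each
six-week cycle (an exact identity, tested to 1e-10).  A short variant
(4 weeks of treatment in a 6-week horizon, two-week on/off periods) is
bundled as a config.  `compare_protocols()` runs control, continuous and
intermittent arms with identical everything else on a wild-type tumor
(`mu1 = 0`, domain `R = 1.2` cm) and reports end-of-treatment loads, the
ordering, and whether each treated arm relapses after withdrawal.  At the
baseline, continuous dosing suppresses the tumor far below the
intermittent arm at matched dose across the tested `q1` ladder
{2e3, 5e3, 1e4} pg/cm³/day, and both treated arms relapse once the drug
is withdrawn — the drug buys time, it does not cure.

# Parameter estimation

The estimation module inverts *simplified* versions of the model: space
is dropped (the measurements are tissue-level), and over the short
interval between the two measurement days each source term is held at a
constant representative value — the arithmetic mean of its day-1 and
day-5 levels (geometric mean available for robustness studies).  Every
estimator is then a closed form:

* net tumor growth `g`: mean of `ln(V2/V1)/(t2-t1)` over consecutive
  volume pairs; `d_T = ln2 / half-life` (literature input);
  `lamT = g + d_T`;
* linear production (`mu1`, `lam1`, `lamG`): invert
  `du/dt = aS - du` for `a`;
* IL-27-enhanced production `lam2`: same inversion on the combined
  source, subtracting the `lam1` baseline;
* activation `lamE`: invert the CTL balance in the knockout/control arm,
  where no survival cytokine acts and the effective death rate is
  exactly `d_E`;
* survival constants: the knockout/IL-27 arm isolates the IL-27 survival
  factor; a one-dimensional root solve recovers its effective death rate
  `d_eff`, and `K_E1 = Ī27 / (d_E/d_eff - 1)`.  The IL-10 survival
  constant is then set by the constrained ratio `K_E2 = κ·K_E1`
  (default κ = 0.1), reflecting that IL-10 concentrations are far below
  IL-27 concentrations in these experiments; a free two-constant solve is
  numerically ill-conditioned at realistic noise because it is a
  second-order difference of rates, which is why the constraint exists;
* kill rates: the knockout arms carry no IL-10 killing, so their tumor
  decline identifies `eta2`; the competent arm then identifies `eta1`
  after subtracting the IFN-γ contribution.

Genotype contrasts, not curve fitting, do the identification: each
parameter comes from the arm (or arm difference) in which it is the only
unknown.  Missing arms disable only their dependent parameters — the
cascade reports them as unestimable with a reason and leaves upstream
estimates untouched.  There is deliberately no global least-squares or
Bayesian fit to the PDE: the closed-form cascade *is* the method.

# Synthetic observations

`generate_observations()` produces exactly the measurements the cascade
consumes: an exponential tumor-volume series (days 11–20), and per-arm
tumor/CTL densities and cytokine concentrations at days 1 and 5 for the
four genotype arms, with anchors `T(1) = 3e8` cells/cm³ (dense measured
lesion) and `E(1) = 8e6` cells/cm³ (transferred CTL bolus).  Arm
trajectories follow the same simplified constant-source models the
estimators invert, iterated to a self-consistent fixed point so that
every "constant source" equals the two-point average of the trajectory
it generates.  On noiseless output the cascade therefore recovers the
generating parameters to round-off — the design closes the
generate-then-estimate loop exactly, which is what makes the recovery
test a sharp correctness check on the estimator algebra rather than a
measure of model mismatch.  The full nonlinear well-mixed dynamics are
available separately (`simulate_wellmixed()`), and deliberately *not*
used as the observation generator: data from the full model carry a
quasi-staticity bias of several percent into the closed-form inversions,
which would blur algebra errors with model error.

Noise is multiplicative lognormal, median-preserving on the log scale,
with a designed CV (default 10%) — observations are positive
concentrations and counts, and assay error scales with the measurement.
All randomness flows through the design's single seed; CV = 0 is exactly
deterministic.  What the generator does **not** emulate: flow-cytometry
or imaging raw data, between-animal heterogeneity beyond the lognormal
CV, correlated assay errors, or spatial sampling effects.  Passing
recovery tests therefore demonstrate estimator correctness and noise
robustness under the stated error model, not robustness to structural
mismatch with real tumors.

At 10% CV over 200 replicates the median relative error of every
estimated parameter stays below 15% (the survival constant `K_E1` is the
widest, as expected for a constant identified through a ratio of decay
rates); the per-parameter values are written by `scripts/acceptance.R`.

# Sensitivity analysis

`run_sensitivity()` follows the standard Latin-hypercube / partial rank
correlation recipe.  Thirteen parameters are analyzed — the three
per-cell production rates, the CTL activation rate, five half-saturation
constants, the CTL death rate, the two kill rates, and the carrying
capacity — each over a ±2-fold range around baseline (ranges are a
config input).  The output functional is the treated/control tumor ratio:
two simulations differing only in `mu1` (baseline versus 0), evaluated at
day 15; ratios below 1 mean IL-27 promotes rejection.  The well-mixed
surrogate is the default for large samples (the PDE mode is available
and used for small n); the evaluation time, radius and mode are recorded
in the result.  PRCC ranks all columns, removes the linear rank
dependence on the other twelve parameters by regression, and correlates
the residuals; p-values use the Student-t approximation with
`df = n - 2 - k`.  Ties get average ranks; a parameter whose ranks are
exactly explained by the others has no remaining association and reports
a PRCC of 0.

Two findings from the baseline analysis deserve note (both recomputed by
`scripts/acceptance.R`).  First, the dominant effects are unambiguous:
the IL-10 axis (`lam2` negative, `K_I27_10` and `K_kill10` positive,
`eta1` negative), the CTL axis (`lamE` negative, `d_E` and `K_E1`
positive) and the carrying capacity (negative) control the treatment
effect.  Second, the IFN-γ kill parameters show a sign inversion between
local and global sensitivity: at the baseline point, increasing `eta2`
strengthens rejection (negative local elasticity at every evaluation
day), but globally over the sampled hypercube its PRCC is positive.  The
mechanism is a self-defeating-kill feedback specific to *transfected*
tumors: IFN-γ killing removes tumor cells that are themselves the IL-27
source, and the collapse of IL-27 throttles the far stronger IL-10 kill
channel.  The feedback grows with the production rate (the PRCC moves
monotonically toward zero as `mu1` is reduced).  Interpreting IFN-γ
sensitivities for transfected-tumor therapy therefore requires
distinguishing local from global questions; the four robust sign
conclusions above do not suffer from this ambiguity.

# Problem sizes and numerical conventions

Defaults and the sizes used by the test suite and acceptance script,
chosen as desk-scale study conditions:

* grid: `N = 200` nodes default; `N = 100` for the dose ladder,
  `N = 96` (R = 1.2 cm) for protocol studies, `N ∈ {50,100,200}` for the
  convergence study;
* horizons: 15 days for transfected-tumor runs (outputs at days 3, 9,
  15), 30 weeks for the long protocol study (treatment ends at week 18);
* recovery study: 200 noisy replicates at CV 10%;
* sensitivity: n = 5000 samples is the analysis-fidelity default;
  n = 2000 in the acceptance script and n = 200 × 3 seeds in the
  reduced test;
* tie-breaks and degenerate inputs: average ranks in PRCC; zero killer
  or producer concentrations raise explicit unidentifiability errors
  rather than returning infinities; the effective-death root solve
  brackets `[1e-8, 100]`/day and reports failure outside it.

# Known limitations

* The model omits angiogenesis, innate immunity, macrophage/Treg
  compartments, immune exhaustion, and pharmacokinetics beyond the
  stated exponential delivery profile; conclusions about dosing apply to
  tumors where local cytokine delivery is the dominant constraint.
* The baseline parameterization is a coherent package default informed
  by literature magnitudes, not a fit to any single data set; recovery
  tests validate the estimators, not the baseline's biological truth.
* The estimators assume quasi-static sources between measurement days;
  applying them to strongly non-stationary intervals biases estimates
  (this is inherent to the two-time-point design, not to the
  implementation).
* One-dimensional radial geometry cannot represent invasive fronts,
  necrotic cores with irregular shape, or vascular hot spots.
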