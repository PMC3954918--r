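# il27sim

Spatial modeling of IL-27-induced anti-tumor CD8⁺ T cell responses.

IL-27 is an IL-12-family cytokine under investigation as a cancer
immunotherapy agent: it is far less toxic than IL-12, enhances the survival
of tumor-antigen-specific CD8⁺ T cells, and upregulates their IL-10
secretion — which, in this setting, acts as an anti-tumor cytokine — while
inhibiting their IFN-γ secretion.  `il27sim` is an R package for scientists
studying this network.  It simulates a spherically symmetric tumor in
tissue, compares IL-27 injection schedules, recovers kinetic parameters
from two-time-point mouse measurements, and quantifies which parameters
control the treatment effect.

## The model

Five radially symmetric fields on a ball of radius R — IL-27 ($I_{27}$),
IL-10 ($I_{10}$), activated CD8⁺ T cells ($E$), IFN-γ ($G$), tumor cells
($T$) — obey a reaction–diffusion system (no-flux boundaries, units
day/cm/pg/cells):

$$\partial_t I_{27} = D_{I27}\Delta I_{27} + \mu_1 T - d_{I27} I_{27} + f(r,t)$$

$$\partial_t I_{10} = D_{I10}\Delta I_{10} + \lambda_1 E + \lambda_2 E\,\frac{I_{27}}{K_{I27,10}+I_{27}} - d_{I10} I_{10}$$

$$\partial_t E = D_E\Delta E + \lambda_E\,\frac{T}{K_T+T} - d_E\,\frac{E}{1 + I_{27}/K_{E1} + I_{10}/K_{E2}}$$

$$\partial_t G = D_G\Delta G + \lambda_G E\,\frac{K_{I27,G}}{K_{I27,G}+I_{27}} - d_G G$$

$$\partial_t T = D_T\Delta T + \lambda_T T\left(1-\frac{T}{T_{max}}\right) - d_T T - \eta_1 T\,\frac{I_{10}}{K_{kill,10}+I_{10}} - \eta_2 T\,\frac{G}{K_{kill,G}+G}$$

IL-27 enters either from transfected tumor cells ($\mu_1 > 0$) or from a
therapeutic source $f(r,t) = q(t)\,e^{-\gamma(R-r)}$ delivered at the tissue
boundary.  Around the PDE the package provides:

* a conservative finite-volume method-of-lines solver (`simulate()`) whose
  no-flux diffusion conserves mass to round-off by construction;
* injection protocols (`injection_protocol()`, `compare_protocols()`):
  continuous dosing versus intermittent dosing at double amplitude and
  matched cumulative dose;
* closed-form two-time-point estimators (`estimate_all()` and friends) that
  invert simplified well-mixed subsystems for the production, activation,
  growth, death and killing rates, using the four genotype arms of the
  source experiments (IL-10-competent/knockout CTLs × IL-27-secreting/
  control tumors) as identifying contrasts;
* a synthetic observation generator (`generate_observations()`) with seeded
  multiplicative lognormal noise, for end-to-end recovery studies;
* Latin hypercube + partial-rank-correlation sensitivity analysis
  (`run_sensitivity()`) of the treated/control tumor ratio.

## Worked example

Dose study: four transfected-tumor simulations with increasing per-cell
IL-27 production, day-15 totals over the ball:

```r
library(il27sim)
p    <- il27_parameters()            # baseline parameter set
grid <- build_grid(R = 0.5, N = 100)
finals <- sapply(mu1_ladder(), function(m) {
  tr <- simulate(update_parameters(p, mu1 = m), grid, t_end = 15)
  tr$totals[nrow(tr$totals), ]
})
signif(finals[c("T", "E", "I10"), ], 3)
#>         none    small moderate    large
#> T   2.47e+07 2.29e+07 2.06e+07 1.75e+07
#> E   3.43e+04 3.98e+04 4.64e+04 5.45e+04
#> I10 7.59e-02 1.43e-01 2.39e-01 3.75e-01
```

Reading the columns left to right: as IL-27 production rises, the total
tumor burden falls by 29% while CD8⁺ T cells and IL-10 totals rise — the
qualitative signature of IL-27-driven tumor rejection.  The well-mixed
treated/control contrast is stronger still:

```r
tumor_ratio(p)          # treated / control tumor density at day 15
#> [1] 0.2205783
```

Recovering parameters from synthetic noiseless observations closes the
loop exactly:

```r
obs <- generate_observations(p, observation_design(cv = 0))
est <- estimate_all(obs, fixed = fixed_constants(p), kappa = 0.1)
signif(est$estimates[c("g", "mu1", "lamE", "eta1", "eta2")], 4)
#>         g       mu1      lamE      eta1      eta2 
#> 3.434e-01 1.000e-05 5.800e+05 1.000e+00 4.000e-01
```

Configured pipelines (the four bundled YAML files under
`inst/configs/`) run through `execute_run()`, or from a shell via
`inst/cli/il27sim.R`.

## Package layout

| Path | Contents |
| --- | --- |
| `R/parameters.R`, `R/nondimensional.R` | parameter data model, units, scaling |
| `R/reaction.R`, `R/grid.R`, `R/solver.R` | kinetics, finite volumes, PDE solver |
| `R/protocols.R` | injection source and schedule comparison |
| `R/estimation.R`, `R/observations.R` | estimator cascade and synthetic data |
| `R/sensitivity.R` | LHS sampling, PRCC, tumor-ratio functional |
| `R/reporting.R` | run configs, artifact export, manifests |
| `vignettes/il27-tumor-model.Rmd` | methods vignette |
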