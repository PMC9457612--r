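# dcphase

Phase-field simulation of nucleated Wnt destruction-complex condensates
and beta-catenin processing, plus FRAP recovery-curve analysis.

## The problem

The destruction complex (DC) — the Axin/APC scaffolds with the kinases
CK1alpha and GSK3beta — phosphorylates beta-catenin in two sequential
steps (priming at S45, then completion), marking it for degradation. At
endogenous concentrations the DC lives in a liquid condensate nucleated
at the centrosome rather than demixing spontaneously. `dcphase` is for
quantitative cell biologists and biophysical modellers who want to ask:
*how much does nucleated condensation accelerate beta-catenin
processing, and how does that depend on kinetics, interaction strength,
and nucleator size?*

## The model

Seven volume fractions φ₁…φ₇ (GSK3β, CK1α, β-cat, P1-β-cat, P4-β-cat,
cytoplasm, nucleator) evolve on a closed 2-D grid by a reactive
multicomponent Cahn–Hilliard system:

    ∂φᵢ/∂t = ∇·M∇μᵢ + Rᵢ ,   μᵢ = ∂F/∂φᵢ − λ∇²φᵢ ,
    F = Σ_{i<j} χᵢⱼ φᵢ² φⱼ² ,

with pairwise interactions χ restricted to binding (−0.1), neutral (0)
and separating (+2) classes — the scaffold is implicit in these — and
second-order mass-action reactions
β-cat →(CK1α, k₁)→ P1 →(GSK3β, k₂)→ P4. The centrosome is a static disk
of nucleator material with binding interactions toward the DC clients.
Matched nucleated/non-nucleated runs (shared seed) yield the
**nucleation efficiency**, the ratio of the integrated P4:β-cat ratios
between the twins; the package also implements the rate/χ/size parameter
scans and single-exponential FRAP fitting, f(t) = a(1−e^(−bt)) with
τ½ = ln2/b. The methods vignette
(`vignettes/destruction-complex-phase-field.Rmd`) derives the
discretisation and documents every default.

## Worked example

```r
library(dcphase)

pair <- gen_dc_scenario(seed = 1)      # default 100x100, 100-step study
tn <- run_sim(pair$nucleated)
tf <- run_sim(pair$free)
nucleation_efficiency(tn, tf)
#> <efficiency_result> step 100: P4/bcat nucleated 0.0001109, free 7.873e-05, efficiency 1.409

fin <- snapshot_at(tn)
mask <- nucleator_mask(fin$grid, pair$nucleated$nucleator)
partition_coefficient(fin, mask, "GSK3B")
#> [1] 1.765743

tail(species_timecourse(tn), 2)
#>     step   time    bcat   bcat_p1   bcat_p4   total
#> 100   99 0.0495 0.04937 0.0006160 5.360e-06 0.04999
#> 101  100 0.0500 0.04937 0.0006223 5.475e-06 0.04999

fit_frap(gen_frap_trace(a = 0.8, b = 0.05, noise_sd = 0.05, seed = 2))
#> <frap_fit> a = 0.7988, b = 0.0516 /s, tau_half = 13.43 s (SSE 0.0985, converged)
```

Read: the nucleated twin processed β-catenin ~41% more completely than
its identically seeded free twin (efficiency 1.409 > 1), because GSK3β
(like the other clients) is enriched ~1.8-fold in the droplet around the
nucleator; the β-cat chain total is conserved (`total` column) while the
phosphorylated pools grow. The FRAP fit recovers the generating
parameters (a = 0.8, b = 0.05 s⁻¹) from a 5%-noise trace.

Parameter scans return tidy tables with provenance columns:

```r
scan_rates(c(5, 50, 500), c(5, 50, 500),
           do.call(run_config, list(grid = list(nx = 64, ny = 64))), seed = 1)
scan_client_chi(c(2, 1, 0), "GSK3B", ...)
scan_nucleator_size(c(0.02, 0.08, 0.15), ...)
```

A command-line wrapper (`inst/cli/dcphase.R`) exposes `simulate`,
`scan`, `frap` and `fixtures` subcommands over YAML configs, writing
diagnostics/snapshot CSVs and a provenance JSON.

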