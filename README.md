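# actstate

Bayesian classification of microbial gene activity states from
expression compendia.

Given a genes × experiments matrix of normalized log expression
ε<sub>ij</sub>, `actstate` estimates, for every gene *i* and experiment
*j*, the posterior probability a<sub>ij</sub> that the gene is *active*
(its product participates in a functioning cellular process) rather
than *inactive* (basal production). The estimate comes from a
two-component equal-variance Gaussian mixture,

&nbsp;&nbsp;&nbsp;&nbsp;ε<sub>i</sub> ~ (1 − π) N(μ₀, σ) + π N(μ₁, σ),  μ₀ ≤ μ₁,

fitted by Gibbs sampling with conjugate priors (μ₀ ~ N(8, var 3),
μ₁ ~ N(9, var 3), σ² ~ IW(3, 1), π ~ Beta(5, 5)), either per gene
(**UniMM**) or per operon (**MultiMM**), where all genes of an operon
share one activity state per experiment — so within-operon calls can
never conflict, and evidence pools across the operon's genes.

Around the samplers the package provides the full workflow:

* **BIC screening** of genes/operons that never change state
  (equal-variance EM, 12-point margin) and a **similarity-based
  multiple-imputation fallback** that borrows fitted mixtures from
  genes with matching parameters (a<sub>ij</sub> = 0.5 when no donor
  exists);
* **baselines**: median threshold (MT), trichotomous threshold (TT,
  40th/60th percentiles), rank-based (RB);
* a **ground-truth simulator** for operon-structured compendia
  (26.3% single-component operons, π ~ Unif(0.2, 0.8), parameters
  calibrated to fitted real-compendium quartiles);
* **evaluation statistics**: squared deviation, consistency
  c<sub>ij</sub>, confidence strata, within-operon consistency classes,
  pathway-component Welch tests, flux correlation;
* **gene–reaction rule engines**: reaction states → gene predictions
  p<sub>ij</sub> (isozyme/complex logic, contradictions resolve to
  active) and gene activities → reaction scores q<sub>ij</sub>
  (min over complex subunits, max over isozymes).

## Worked example

Simulate a small ground-truth compendium, run the full pipeline
(screen → fit → impute), and evaluate against the truth:

```r
library(actstate)

design <- build_sim_design(n_operons = 20, n_experiments = 400,
                           single_component_fraction = 0.25, seed = 42)
sim <- simulate_compendium(design)
dim(sim$compendium)
#> [1]  35 400

res <- run_pipeline(sim$compendium, sim$operon_map, method = "multimm",
                    cfg = gibbs_config(seed = 42), truth = sim$alpha)

round(res$a[1:3, 1:4], 3)       # posterior activity probabilities
#>       e0001 e0002 e0003 e0004
#> g0001     0     0     0     0
#> g0002     0     0     0     0
#> g0003     0     0     0     0

round(res$report$mean_consistency, 3)   # agreement with the truth
#> [1] 0.876
round(res$report$sensitivity, 3)
#> [1] 0.836
round(res$report$specificity, 3)
#> [1] 0.917

oc <- operon_consistency(res$a, sim$operon_map)
table(oc$class)                 # no within-operon conflicts, ever
#>      consistent very_consistent
#>             508            2692

res$fits[[1]]                   # one operon's fitted mixture
#> Gaussian mixture (2 components)
#>   pi    : 0.3472
#>   mu0   : 9.290 8.899 8.176
#>   mu1   :  9.983 10.284  9.711
#>   sigma : 0.4589 0.5185 0.5619
```

The first three genes form one operon: their rows of `res$a` are
identical by construction. The fitted mixture shows per-gene state
means (note each gene has its own activity threshold) with a shared
mixing proportion ≈ 0.35 — this operon is active in roughly a third of
the simulated conditions.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/actstate.R`:

```sh
Rscript inst/scripts/actstate.R simulate --operons 50 --experiments 200 \
    --seed 1 --out-prefix sim/
Rscript inst/scripts/actstate.R pipeline --expression sim/expression.tsv \
    --operons sim/operons.tsv --method multimm --seed 1 --out sim/a.tsv
Rscript inst/scripts/actstate.R evaluate --activity sim/a.tsv \
    --truth sim/truth.tsv --operons sim/operons.tsv --report sim/report.json
```

## Documentation

The methods vignette (`vignettes/activity-states.Rmd`) describes the
model and priors, the Gibbs sweep, screening/imputation, the
simulator's assumptions and what it does not emulate, numerical
conventions (label switching, seeding, boundary handling), and known
limitations.
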