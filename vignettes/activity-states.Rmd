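---
title: "Classifying microbial gene activity states with Gaussian-mixture Gibbs samplers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying microbial gene activity states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actstate)
```

## The model

Many downstream analyses of microbial transcriptomics — metabolic model
integration in particular — need a binary judgement per gene and
condition: is the gene *active* (its product participates in a
functioning cellular process) or *inactive* (basal production only)?
`actstate` treats this as inference on a latent state. For gene $i$ with
log-scale, RMA-like expression values $\epsilon_{ij}$ observed across
$n$ experiments,

$$\epsilon_i \sim (1 - \pi)\,N(\mu_0, \sigma) + \pi\,N(\mu_1, \sigma),$$

where $\mu_0 < \mu_1$ are the inactive- and active-state means, $\sigma$
is a shared within-state standard deviation, and $\pi$ is the fraction
of experiments in which the gene is active. Forcing $\sigma_0 =
\sigma_1$ trades a little flexibility for markedly better chain
convergence and robustness to outliers, and encodes the assumption that
measurement plus biological noise is comparable in both states. The
quantity of interest is $a_{ij}$, the posterior probability that gene
$i$ is active in experiment $j$.

Two samplers produce $a_{ij}$:

* **UniMM** fits each gene independently.
* **MultiMM** fits each *operon* jointly: all $p$ genes of an operon
  share one activity indicator per experiment, with per-gene means and
  variances and zero within-state covariance (the joint density is a
  product of univariate Gaussians). Because inference is about the
  operon as a whole, every gene of an operon receives identical
  $a_{ij}$ — within-operon inconsistencies are impossible by
  construction, and evidence pools across genes, sharpening calls that
  would be uncertain gene-by-gene.

## Priors and the Gibbs sweep

Conjugate priors keep every full conditional in closed form:
$\mu_0 \sim N(8, \mathrm{var}\,3)$, $\mu_1 \sim N(9, \mathrm{var}\,3)$,
$\sigma^2 \sim \mathrm{IW}(\Psi = 3, \nu = 1)$ (univariate; the
multivariate sampler uses an identity scale with $\nu = p + 2$), and
$\pi \sim \mathrm{Beta}(5, 5)$. The prior means 8 and 9 sit near the
center of typical RMA-normalized expression (values mostly between 4
and 16); the Beta(5, 5) prior is symmetric, mildly informative, and
keeps $\pi$ off the boundaries. A note on notation: the $\mu$ prior is
parameterized by *variance* 3 — the conjugate update uses precision
$1/3$ — which is the internally consistent reading of the update
formulas this model family uses.

Each chain starts at $\hat\mu_0 = 8$, $\hat\mu_1 = 9$, $\hat\sigma = 1$,
$\hat\pi = 0.5$ (a fixed, neutral initialization) and iterates, for
$k = 1 \dots K$:

1. compute responsibilities $b_{ij}$ of the active component under the
   current parameters (in log space, clipped to
   $[10^{-12}, 1 - 10^{-12}]$ before sampling);
2. draw binary indicators $I_{ij} \sim \mathrm{Bernoulli}(b_{ij})$;
3. redraw $\mu_0, \mu_1$ from their normal posteriors (the data term
   uses the *assigned cluster's* size and mean), $\sigma^2$ from the
   inverse-gamma posterior with shape $(\nu + n)/2$ and scale
   $(\Psi + SS)/2$ (the residual sum $SS$ pools both clusters over all
   $n$ experiments), and $\pi$ from
   $\mathrm{Beta}(5 + |C_\mathrm{active}|, 5 + |C_\mathrm{inactive}|)$.

The parameters carried into the next sweep are the *sampled* values — a
standard Gibbs chain — not running point estimates; posterior means are
reported only in the final fit summary. Label switching is resolved
deterministically: whenever a sweep's draws violate $\mu_0 \le \mu_1$
(for operons: $\mathrm{mean}(\vec\mu_1 - \vec\mu_0) < 0$), the labels
are swapped, the indicators complemented, and $\pi \mapsto 1 - \pi$.

Defaults are $K = 500$ iterations with burn-in $b = 50$; shorter chains
tend to give visibly less stable $a_{ij}$. The estimate averages the
indicators of sweeps $b + 1, \dots, K$ — exactly $K - b$ terms, so every
$a_{ij}$ lies on the grid $\{0, 1/(K-b), \dots, 1\}$.

For the multivariate sampler the inverse-Wishart posterior is applied
per gene as inverse-gamma with shape $(p + 2 + n)/2$ and scale
$(1 + SS_g)/2$ — the diagonal-marginal convention for an identity-scale
prior. This is a convention choice: with diagonal covariance and a
diagonal scale matrix the gene-wise updates decouple, and the extra
$p + 1$ prior degrees of freedom are negligible against compendium-scale
$n$.

### Seeding and reproducibility

Each gene (or operon) gets its own RNG stream, seeded by a 32-bit hash
of the unit identifier combined with the global seed. Subsetting or
reordering a compendium therefore leaves the results of the remaining
units bit-identical. One consequence worth knowing: indicator draws are
positional within a unit's stream, so permuting *experiments* permutes
$a_{ij}$ only in distribution, not bit-exactly; the same applies to a
constant expression row, whose entries receive statistically
exchangeable — not identical — estimates. The test suite checks these
properties at Monte-Carlo tolerance.

## Screening and imputation

A two-component fit is meaningless for a gene that never changes state.
Before fitting, every unit is screened: equal-variance mixtures with 1
and 2 components are fitted by EM (5 restarts from k-means++-style
initial centers, under a derived seed) and compared by
$\mathrm{BIC} = 2\,\ell - d \log n$ (higher is better; $d = 2p$ for one
component, $3p + 1$ for two). The 1-component model is called only when
its BIC wins by at least 12 points — a conventional "very strong
evidence" margin, deliberately conservative about taking a gene out of
the mixture machinery.

Two numerical facts about this margin are worth recording. First, for a
single gene the BIC penalty difference is $2\log n$, which only exceeds
12 when $n > e^6 \approx 403$: at smaller compendium sizes a singleton
gene cannot be called 1-component at all under the default margin (the
screen then simply leaves it in the 2-component path, which is safe).
Second, even at $n = 907$ the slack over the margin is
$2\log 907 - 12 \approx 1.6$ log-likelihood-ratio units, and the
maximum-likelihood gain of a spurious second component on truly
unimodal data exceeds that in a substantial fraction of datasets — a
well-known property of Gaussian-mixture likelihood ratios. The margin
therefore biases the screen toward keeping genes in the 2-component
path; with plain best-BIC selection (margin 0) unimodal genes are
called 1-component essentially always. Both behaviors are exercised in
the tests.

Genes screened as 1-component get activities by a similarity-based
multiple-imputation fallback: the single-component fit $(\bar x, s)$ is
compared against the fitted 2-component models of all other genes, and
any gene whose $\hat\mu_0$ or $\hat\mu_1$ lies within $\pm 0.1$ of
$\bar x$ while $\hat\sigma$ lies within $\pm 0.1$ of $s$ (inclusive
bounds) donates its mixture: the target's expression row is scored
under each donor model and the resulting $a$ vectors averaged. With no
donors, $a_{ij} = 0.5$ throughout — an explicit "don't know". For a
1-component *operon*, each gene is imputed separately and the per-gene
vectors averaged, so the operon again gets identical rows; the operon
is labelled always-active when the mean imputed $a$ exceeds 0.5,
always-inactive below, and unresolved at exactly 0.5 (the tie rule is a
package choice; ties are measure-zero in practice).

## Baselines

Three standard estimators are included for comparison, all
column-wise (per experiment): **MT** thresholds at the per-experiment
median (optionally the mean); **TT** adds an uncertain band, scoring 0
below the 40th percentile, 0.5 up to the 60th, 1 at or above it (the
three bins partition the line; percentiles are type-7 empirical
quantiles); **RB** returns within-experiment ranks over $m$ with
average ranks for ties. Deterministic identities connect them:
dichotomizing RB at 0.5 reproduces MT, and TT with both percentiles at
50 *is* MT. These identities, and the fact that every TT low-confidence
cell sits exactly at 0.5 (forcing 50% consistency against any binary
truth), are asserted in the acceptance tests.

## The simulator

`build_sim_design()` + `simulate_compendium()` generate ground-truth
compendia in the image of a large *E. coli* microarray collection:
operons default to ~71.6% singletons (sizes 1–5 follow a configurable
categorical distribution); 26.3% of operons are single-component, split
evenly between always-active and always-inactive; two-component operons
draw $\pi \sim \mathrm{Unif}(0.2, 0.8)$ ("Unif" mode) or take fitted
parameters ("Fit" mode). Stand-in parameter distributions —
$\mu_0 \sim N(8.1, 0.8)$, separation
$\delta \sim N(1.1, 0.7)$ truncated at 0.3, $\sigma \sim
\mathrm{Unif}(0.3, 0.6)$ — are calibrated to the quartiles of fitted
mixtures reported for real compendium data ($\hat\mu_0$ median 8.08,
$\hat\mu_1$ median 9.22, $\hat\sigma$ median 0.45); they are a
calibration, not an empirical copy. Activity is assigned as a fixed
count: $\mathrm{round}(n\pi)$ experiments drawn uniformly at random
become active for the whole operon, so the realized active fraction is
exact by construction.

What the simulator does *not* emulate: array-level artifacts,
correlated noise across genes outside operons, non-Gaussian state
distributions, and condition structure (replicates, time series).
Passing tests on simulated data therefore demonstrate correctness of
the inference machinery under the model's own assumptions, not
robustness to real-data violations of them.

## Evaluation statistics

Against a binary reference (simulated truth $\alpha_{ij}$ or
model-derived predictions $p_{ij}$, which may be missing):
squared deviation $d^2_{ij} = (a_{ij} - \mathrm{ref}_{ij})^2$ with
per-experiment root-mean summaries; the consistency score $c_{ij}$
(1 concordant, 0 discordant, 0.5 when $a_{ij} = 0.5$ exactly), whose
subset means give sensitivity and specificity; confidence strata
(high $a < 0.2$ or $a > 0.8$; medium $0.2 \le a < 0.4$ or
$0.6 < a \le 0.8$; low $0.4 \le a \le 0.6$ — the boundary $a = 0.4$ is
assigned to "low" so the strata partition $[0,1]$); and within-operon
classes for multi-gene operons (*inconsistent*: some gene above 0.6 and
another below 0.4; *very consistent*: all above 0.8 or all below 0.2;
*consistent* otherwise, with inconsistent taking precedence).
In the consistent-and-correct summary an operon call at exactly
$a = 0.5$ cannot be dichotomized and counts as not-correct, mirroring
the $c_{ij}$ convention. Pathway-component differential activity uses a
Welch two-sample $t$-test on per-experiment component means (the
unequal-variance form is the safer default when group variances are
unknown); flux association uses Pearson correlation against
square-root-transformed absolute fluxes with a Fisher-z interval.

## Gene–reaction mapping

Reaction-level activity states $r_{ij}$ (from flux variability bounds:
active iff the lower bound is strictly positive) map to gene-level
predictions $p_{ij}$ by association kind — active single-gene or
complex reactions mark their genes active; inactive single-gene or
isozyme reactions mark their genes inactive; active isozyme and
inactive complex reactions predict nothing (responsibility cannot be
localized). A gene collecting both votes resolves to active: a
multi-role gene can be active yet perform only some roles. Resolution
is set-level, hence order-independent and idempotent. In the reverse
direction, gene activities aggregate to reaction scores $q_{ij}$: the
gene's own $a$ for single-gene reactions, the minimum over subunits for
complexes, the maximum over isozymes; genes without estimates are
ignored and fully uncovered reactions dropped. Unpredicted cells are
explicit missing values, never 0.5, so they are excluded from — rather
than diluting — downstream consistency summaries.

## Problem sizes and runtime

A single gene's chain ($K = 500$, $n = 200$) runs in roughly 0.1 s; a
full pipeline on 50 operons × 200 experiments, including screening and
imputation, takes well under a minute on one CPU. The test suite and
the reproduction script use compendia of 20–60 operons and 100–400
experiments — large enough for the binomial and recovery tolerances
they assert, small enough to run interactively.

## Known limitations

* The operon model requires hard membership; partial or uncertain
  co-regulation (regulons, multi-transcription-unit operons) is out of
  scope.
* No unequal-variance or >2-component mixtures.
* The imputation fallback averages point imputations only; it does not
  propagate between-donor variance.
* RNA-seq data would need upstream normalization to an RMA-like
  log scale before these priors are sensible.
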