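---
title: "Cross-study replication and coupled signature scoring: methods"
author: "coupledDE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study replication and coupled signature scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coupledDE)
```

# The problem

Case-control studies of whole-blood gene expression are notoriously hard to
replicate: single-study gene lists at conventional thresholds are dominated
by noise, and the same disease analyzed on two cohorts often yields almost
disjoint "significant" genes. `coupledDE` implements an analysis strategy
that takes replication as the primary object: two independent case-control
studies are analyzed identically, and a gene is called only when it is
significant in *both* studies at a threshold chosen so that the number of
joint calls is demonstrably larger than coincidence. The replicated,
sign-concordant genes then define two signatures (UP = overexpressed in
cases, DOWN = underexpressed), and each subject is scored on a single axis —
the *bioscalar* — that captures the coupling between the two signatures at
the level of the individual.

The motivating application is immune dysregulation in depression, where the
UP list tracks innate/myeloid activation and the DOWN list adaptive/lymphoid
function; within this package the two lists are simply disjoint gene sets,
and every stage is generic.

# Per-study differential expression

## Model

For each gene $i$ and sample $j$ the log2 expression is modeled as

$$ y_{ij} = \beta_{i0} + \beta_i^{Gr}\,\mathrm{case}_j + \beta_i^{B}\,\mathrm{batch}_j
 + \beta_i^{Ge}\,\mathrm{sex}_j + \beta_i^{Ag}\,\mathrm{age}_j
 + \beta_i^{An}\,\mathrm{anxiety}_j + \varepsilon_{ij},
 \qquad \varepsilon_{ij} \sim N(0, \sigma_i^2). $$

`buildDesign()` uses treatment coding with fixed reference levels (control,
batch 1, male, anxiety 0), so the group coefficient is directly the
case-minus-control log2 fold change; this matches the identifiability
constraint of setting the first level of each factor to zero. Sum coding
would estimate the same contrast but obscure it. The covariate list is a
parameter: dropping `anxiety` or adding `bmi` reproduces the usual
sensitivity analyses without touching any other stage.

## Empirical-Bayes moderation

Per-gene residual variances $s_i^2$ (with common residual df $d$) are
shrunk toward a prior $\sigma_i^2 \sim s_0^2 d_0/\chi^2_{d_0}$:

$$ \tilde s_i^2 = \frac{d_0 s_0^2 + d\, s_i^2}{d_0 + d}, \qquad
   \tilde t_i = \frac{\hat\beta_i^{Gr}}{\sqrt{c_g\,\tilde s_i^2}}
   \sim t_{d_0 + d} \ \text{under } H_0, $$

where $c_g$ is the group-column diagonal of $(X^\top X)^{-1}$.
`estimateVariancePrior()` fits $(d_0, s_0^2)$ by method of moments on
$\log s_i^2$: under the scaled-$F$ sampling model the excess variance of
$\log s_i^2$ beyond $\psi'(d/2)$ equals $\psi'(d_0/2)$, which is inverted by
bisection to an absolute tolerance of $10^{-8}$. Numerical policy:

* excess $\le 0$ flags $d_0 = \infty$ (every $\tilde s^2 = s_0^2$); finite
  solutions are capped at $10^6$;
* exactly identical variances (a degenerate input no hierarchical model
  generates) return a point prior at the common value, so shrinkage becomes
  a no-op instead of inventing a scale correction from moments the data
  cannot support;
* zero variances are excluded from estimation but still shrunk, receiving
  $\tilde s^2 = d_0 s_0^2/(d_0+d)$;
* $d_0 = 0$ is admitted as the no-shrinkage limit, in which $\tilde t$
  equals the ordinary $t$ exactly (this limit is tested to machine
  precision);
* p-values are floored at the smallest positive double, never 0.

## Permutation p-values

`permutationPvalues()` permutes case/control labels within batch strata
(batch being the largest nuisance factor, stratifying on it preserves its
confounding structure under the null), rebuilds the group column, refits,
and recomputes the moderated $t$ with the *same* prior as the observed
analysis. The p-value is $(1 + \#\{|t^\ast| \ge |t|\})/(1 + B)$, floored at
$1/(B+1)$. With `exhaustive = TRUE` all distinct relabelings are enumerated,
which reproduces the exact permutation test on small designs. Ties between
$|t^\ast|$ and $|t|$ (sign-flipped relabelings produce them up to float
noise) are counted as exceedances using a $10^{-12}$ relative tolerance.

A caveat worth knowing: the permutation law conditions on each gene's
observed variance while the asymptotic law integrates over it, so the two
agree closely only when the statistic is mostly self-studentized (moderate
$d_0$). With a near-infinite prior the moderated $t$ has a fixed
denominator and the two p-values can differ by several percent per gene on
homoscedastic data; this is a property of the statistics, not a defect of
either computation.

## Module eigengenes

`moduleEigengene()` standardizes module genes, takes first
principal-component scores scaled to unit variance, orients them to
correlate positively with the module's mean standardized profile (with a
first-gene tie-break for the two-gene anti-correlated case, where PC1 is
orthogonal to the mean profile), and tests case vs control with a Welch
t-test.

# The replication rule

For a threshold $t$ applied to both studies' p-values, let $O_1, O_2$ be
the per-study significant counts, $O_{11}$ the joint count, and
$E_{11} = O_1 O_2 / N$ its expectation under independence. The overlap
ratio is $R(t) = O_{11}/E_{11}$. All three counts are step functions that
change only at observed p-values, so `overlapProfile()` evaluates them
exactly on the sorted union of observed p-values $\le .05$ plus the
endpoint. The threshold $q_2$ is the largest $t \le .05$ at which the two
studies share at least twice as many genes as chance expects.

## Why selection is guarded by a posterior probability

The raw rule "$R(t) \ge 2$ anywhere on the grid" is unusable as a detector:
under two *independent null* studies the first coincidentally-joint gene
arrives at a threshold where $E_{11}$ is approximately exponentially
distributed with mean 1, so with probability $\approx P(\mathrm{Exp}(1) \le
0.5) \approx 39\%$ a single chance coincidence already makes $R \ge 2$ (we
measured 55% of null simulations firing). The instability is purely a
small-count phenomenon: one gene divided by an expectation of one half.

`selectQ2()` therefore requires the ratio rule to hold *credibly*: the 2x2
classification counts $(O_{11}, O_1 - O_{11}, O_2 - O_{11},
N - O_1 - O_2 + O_{11})$ are resampled as Dirichlet proportions, and a
threshold qualifies when $P(R^\ast \ge 2) \ge 0.99$. Cells with zero counts
keep zero mass, so a lone coincidental overlap can never qualify. At real
replication signal the counts are large, the posterior is concentrated far
above 2, and the guarded rule selects the same threshold the raw rule
would; on null data it fires in about 1% of simulations. The literal point
rule remains available (`method = "point"`) and is what the constructed
examples in the documentation illustrate. The default credibility level
0.99 was fixed from this null calibration before the acceptance suite was
frozen.

`consensusSet()` then splits the genes passing $q_2$ in both studies by
fold-change sign; a fold change of exactly zero is routed to the discordant
list rather than either signature. `fisherCombine()` corroborates the
selection with $X^2 = -2(\ln p_1 + \ln p_2) \sim \chi^2_4$ and
Benjamini-Hochberg control (via `stats::p.adjust`), and
`expectedOverlap()` gives the chance-expected intersection of any two gene
lists.

# Gene-set enrichment

`fisherEnrichment()` is the classic independent-term test: one-sided
hypergeometric upper tail per term, with the Table-style columns
*annotated* (set size within the measurement universe), *found* (overlap
with the query) and *expected* (annotated scaled by the query fraction of
the universe). The universe is always caller-supplied — the genes measured
on the platform, not the genome — because enrichment against an inflated
universe fabricates significance. Multiplicity is handled by a flat
Bonferroni flag at $\alpha$ over the number of terms; no term-graph
decorrelation is attempted (that is a different algorithm family with
different semantics). Depletion (`found < expected`) is flagged but never
tested. GMT files are read by direct tab-splitting because the term
description field is part of the report.

# The bioscalar

`signatureScores()` z-scores each signature gene across all samples of a
study and averages within the UP and DOWN lists per subject.
Standardization keeps high-variance genes from dominating and puts the
scores — and the tertile cutoff — on a comparable scale across studies; raw
averaging is available behind `standardize = FALSE` for sensitivity checks.

`fitCouplingLine()` regresses meanDOWN on meanUP *among cases only*: the
coupling is a property of the patient population, and projecting controls
onto the case-derived axis keeps the two groups comparable on a single
scale. `projectBioscalar()` projects every subject orthogonally onto the
line; the bioscalar is the signed arc-length coordinate measured from the
line point nearest the origin, positive toward increasing meanUP. For a
line through the origin this is exactly the distance of the projected point
from the origin; anchoring at the perpendicular foot makes the definition
affine-consistent for lines that miss the origin. Orthogonal (not vertical)
projection is used because both coordinates are noisy measurements of the
same latent axis.

Summaries: Cohen's $d$ with $n-1$ pooled variance weights; ROC AUC as the
Mann-Whitney rank statistic with ties counted one half; and a top-tertile
subgroup rule whose cutoff is the $\lceil 2n/3\rceil$-th order statistic of
the case scores (nearest-rank convention), with scores tied at the cutoff
classified non-inflamed. Sensitivity on the defining subgroup is 1 by
construction and is kept as a tautology guard in the tests; specificity is
the fraction of controls at or below the cutoff.

# The synthetic-data generator

`generateTwoStudies()` emulates two independently conducted case-control
whole-blood studies on a shared probe panel:

* sample frames of 113/57 and 94/100 (cases/controls), 18,863 genes;
* per-gene baselines uniform on log2 [4, 12]; batch, sex and anxiety
  Bernoulli(1/2), age uniform on [20, 65], with additive per-gene Gaussian
  coefficients (sd 0.1 log2 for the binary covariates, 0.002 log2/year for
  age — effects of the size one sees after array normalization, large
  enough that failing to adjust for them is visible);
* 200 shared DE genes with |log2FC| = 0.8 (constant by default), 90/165 of
  them positive, plus 100 study-specific DE genes per study with random
  signs; shared genes carry the same sign in both studies by construction;
* gene variances from the scaled inverse chi-square prior (d0 = 4,
  s0^2 = 0.25 log2^2 — deliberately stressed placeholders, not estimates of
  any real cohort);
* a per-case latent scalar with loading $+\lambda$ on the planted UP genes
  and $-\lambda$ on the planted DOWN genes. $\lambda$ is solved
  analytically (by `uniroot` on a closed-form expression that accounts for
  the z-scoring denominators, the covariate variance and the group-shift
  variance) so that the case-level correlation between mean UP and mean
  DOWN scores approaches `rhoTarget` (default -0.8); the calibration is
  verified empirically to within 0.1 at 100 cases. Targets below -0.995
  are clamped, since -1 is unattainable in the presence of noise;
* Gaussian noise by default; a scaled Student-t switch (`tNoiseDF`)
  supports robustness experiments.

All randomness flows from one master seed through an integer-hash splitting
scheme (`splitSeed()`), so covariates, variances, effects and noise occupy
separate reproducible substreams and any stage can be regenerated alone.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: correlated noise across genes (cell-type
composition drives most of it in whole blood; its absence is why synthetic
effect sizes for the bioscalar saturate, with Cohen's d far above the
0.5-0.7 range seen in practice), probe-level artifacts, normalization
residue, batch nonlinearity, and missingness. The generator validates the
*machinery* — calibration under the null, recovery under planted signal —
not the clinical effect sizes.

# Problem sizes and runtime policy

The test suite exercises the statistical properties at sizes chosen to make
Monte-Carlo error small relative to the tolerances: null calibration of the
replication rule over 50 seeds at 5,000 genes and 40/40 subjects;
planted-recovery over 10 seeds at 5,000 genes with the full 113/57 and
94/100 sample frames; prior recovery at 20,000 genes; coupling recovery
over 20 seeds at 100 cases; oracle comparisons over hundreds to a thousand
randomized small instances. The reproduction script
(`scripts/acceptance.R`) runs the complete pipeline once at the full
18,863-gene default.

# Known limitations

* Only two studies; the rule generalizes but is not implemented for more.
* The credible selection makes `selectQ2` slightly conservative near
  $R = 2$ with thin counts — by design.
* Gene alignment between studies is by intersection of ids; no ortholog or
  probe mapping.
* The bioscalar tertile cutoff is per study; whether to pool is exposed to
  the caller (compute scores per study, pool before `tertileClassify()` if
  desired) rather than decided here.
* Eigengene group tests use Welch's t; no covariate adjustment at the
  module level.

# A minimal run

```{r example, eval = TRUE}
cfg <- list(sim = simConfig(nGenes = 600,
                            study1 = c(cases = 30, controls = 30),
                            study2 = c(cases = 30, controls = 30),
                            nSharedDE = 40, nSpecificDE = c(10, 10),
                            seed = 11),
            seed = 11)
res <- suppressMessages(runPipeline(cfg))
str(res$summary)
```
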