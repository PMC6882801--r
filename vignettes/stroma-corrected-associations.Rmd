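---
title: "Stroma-corrected association analysis: models, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stroma-corrected association analysis: models, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromascan)
```

## The confounding problem

Bulk tumor expression is an average over every cell in the specimen:
cancer cells, fibroblast-like stromal cells, and immune infiltrate. A gene
expressed by fibroblasts — most mesenchymal and EMT-associated genes are —
will read out higher in stroma-rich samples regardless of what the cancer
cells are doing. Because stromal and immune abundance are strongly
positively correlated across tumors, any fibroblast-expressed gene
acquires a spurious positive association with immune content. Conclusions
about a cancer-cell program suppressing (or recruiting) immune cells must
therefore be drawn *after* removing the stromal component.

`stromascan` implements that correction pipeline and, because the real
cohorts it is designed for are large controlled-access datasets, ships a
synthetic cohort generator that realizes the same confounding structure
with known ground truth, so that every stage can be validated end to end.

## The synthetic cohort model

Each bulk sample is a convex mixture of four population profiles —
epithelial cancer, EMT-like cancer, fibroblast/stromal, immune. The
mixture law is linear in linear expression space:

$$ x_{gs} = \log\!\Big(\sum_c f_{sc}\, e^{\mu_{gc}}\Big) + \varepsilon_{gs},
\qquad \varepsilon_{gs} \sim N(0, \sigma^2), $$

followed by per-gene z-scoring across samples, matching the z-score form
in which public cohort expression is distributed. Mixing fractions
$f_{s\cdot}$ are Dirichlet draws whose fibroblast and immune components
are tilted by a shared latent Gaussian before renormalization; this
preserves convexity exactly while inducing the positive stromal–immune
abundance correlation observed in real cohorts. An *anchor* gene (plus a
configurable block of co-regulated "program" genes) is expressed by both
EMT-like cancer cells and fibroblasts and additionally carries a
per-sample cancer-intrinsic activity $a_s \sim N(0,1)$. A coupling
parameter $\beta$ multiplies the immune mixture weight by $e^{\beta a_s}$:
with $\beta = 0$ the anchor's association with immune content is pure
stromal confounding; with $\beta < 0$ the anchor genuinely suppresses
immune infiltration.

Parameter defaults and the reasoning behind them:

* **Dirichlet concentrations** (epithelial 10, EMT 2, fibroblast 4,
  immune 3): mean fractions of roughly 53/11/21/16%, a plausible
  carcinoma composition with most variance in the stromal and immune
  components.
* **Stromal–immune coupling 1.2** gives a fraction-level Spearman
  correlation near 0.5–0.6, the "highly correlated" regime that makes the
  confounding material.
* **Anchor EMT-cell loading is 0.4× its fibroblast loading.** The anchor
  is still expressed "higher in fibroblasts and EMT-like cells than in
  epithelial cells", but a full-size EMT loading would open a second,
  non-stromal compositional pathway between the anchor and the immune
  fraction (given the fibroblast fraction, EMT and immune fractions
  compete for the remainder), and the partial correlation given true
  stromal content would no longer be near zero at $\beta = 0$. The
  reduced loading keeps the construction a clean realization of the
  stromal-confounding mechanism.
* **Marker blocks are 8% (stromal, immune) and 6% (epithelial, EMT) of
  the gene universe.** Within-sample ranks are competitive: if marker
  blocks dominate a small universe, high stromal content mechanically
  depresses the ranks — and hence the enrichment score — of immune genes.
  Real scoring uses ~141-gene sets among ~20,000 genes, where this
  competition is negligible; small proportions keep the simulated scores
  in that regime.
* **Noise $\sigma = 0.1$** (log scale) and **activity SD 0.5** give marker
  z-scores that track their fraction at Spearman $r > 0.8$ and an anchor
  whose cancer-intrinsic variance is comparable to its stromal variance —
  both features of well-measured bulk data.
* **Survival**: event times are exponential with hazard
  $\lambda_0 e^{\eta}$, $\lambda_0 = 0.01$/month, and the linear predictor
  $\eta$ applies configurable log-hazards to stage (ordinal 1–4), age
  (per year), ER status and the anchor activity. A constant baseline is
  sufficient because Cox estimation is invariant to the baseline shape.
  Censoring is independent of covariates: each sample is censored with
  probability `censoring_rate` at a uniform fraction of its event time.
* **IHC readouts** are $100 f + N(0, 5)$ percentage points, clipped to
  $[0, 100]$ — deliberately noisy, mimicking semi-quantitative pathology
  estimates.

What the generator does *not* emulate: read counts and library-size
effects, batch effects, probe-level microarray structure, more than four
populations, or subtype-specific biology (subtype labels are assigned
independently of expression). Passing tests on this generator therefore
demonstrate that the statistical machinery recovers the truth *under the
stated mixture model*, not that any particular real-data conclusion is
correct.

## Scoring stromal and immune content

Stromal and immune scores are single-sample rank-based enrichment
statistics. Genes are ranked within each sample (rank 1 = highest;
average ranks on ties). Walking the ranked list, set members add a
normalized weight $(N - r_i + 1)^{w} / \sum_{j \in S} (N - r_j + 1)^{w}$
and non-members add $1/(N - |S|)$; the score is the sum over positions of
the difference between the two running sums. The weight exponent defaults
to $w = 0.25$ (the published stromal/immune scoring convention) and is
exposed as a parameter. Being rank-based, scores are exactly invariant
under strictly increasing transforms of the per-sample expression, so
linear versus log input is immaterial.

Numerical edge cases are defined explicitly: a set covering the whole
universe has no miss denominator and scores 0; an empty intersection with
the gene universe is an error naming the set. Note one subtlety of the
weighted walk: because hit weights are renormalized over the set, moving
a single member to a better rank is guaranteed never to decrease the
score only for $w = 0$; for $w > 0$ the redistribution of weight among
members can produce small exceptions. The extremal property — members
occupying exactly the top $|S|$ ranks maximize the score — holds for all
$w \ge 0$.

## Partial Spearman correlation

The core statistic is the partial Spearman correlation of a gene with a
score given confounders: rank-transform everything (average ties),
residualize the ranked gene and the ranked target on the ranked
confounders plus an intercept by least squares, and correlate the two
residual vectors. For one confounder this is algebraically the classical
recursion $(r_{xy} - r_{xz} r_{yz}) / \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}$
— the package tests enforce agreement within $10^{-10}$. P-values use
$t = r\sqrt{\mathrm{df}/(1 - r^2)}$ with $\mathrm{df} = n - 2 - k$.
Confounders are ranked before residualization; the alternative (ranking
only the variables of interest) differs in general, and the
recursion-equivalent convention is the one matching standard partial
rank-correlation implementations.

*Stroma-adjusted expression* — used for median splits and survival
covariates — residualizes the **raw** (unranked) values on the stromal
score, because downstream consumers (Cox models, rank-sum splits) want an
expression-scale covariate, not a rank.

Degenerate inputs are errors, not numbers: constant vectors, rank-
deficient confounder matrices, and variables fully absorbed by the
confounders all fail loudly. Missing values are dropped complete-case per
analysis cell, with the effective $n$ reported per cell. Raw p-values are
reported throughout (a Benjamini–Hochberg helper is available but not
applied to association matrices by default, matching the convention of
reporting per-cell raw p-values).

When the adjustment set is not fixed a priori, `select_confounders()`
offers the conventional screen: univariable linear-model F-test at
p < 0.05 to enter, multivariable p ≥ 0.05 to drop, iterated to stability.
Both thresholds are arguments.

## Signature derivation

The derivation pipeline intersects two independent lines of evidence that
a gene is activated by the anchor's transcriptional program:

1. **Knockdown response**: genes significantly downregulated when the
   anchor is knocked down (strict FDR < 0.05 and log2 fold change < −2).
   The built-in differential test is a per-gene Welch t-test with BH
   correction; externally computed DE tables in the same schema are
   accepted.
2. **Co-expression**: genes with Spearman $r > 0.5$ against the anchor in
   the bulk cohort.

The overlap is tested for enrichment with the hypergeometric upper tail,
evaluated in log space (`phyper(..., log.p = TRUE)`), with a default
universe of 20,000 genes. Finally the stroma-adjusted filter retains only
overlap genes whose partial Spearman correlation with the anchor given
the stromal score stays above 0.5 — removing genes that co-occur with the
anchor only because both track fibroblast content. All fold-change and
correlation thresholds are strict inequalities and are configurable; set
algebra (final ⊆ overlap ⊆ each input set) is asserted on every run. An
empty signature is a clean, explicitly represented outcome.

## Survival analysis

Cox proportional-hazards fits use Efron tie handling by default
(configurable to Breslow) via the standard partial-likelihood machinery
of the `survival` package. Stage enters as a single ordinal numeric
covariate (configurable encoding). The per-gene scan refits the base
multivariate model (stage, age, ER status) plus one gene at a time, in
raw or stroma-adjusted mode; per-gene failures and collinearity are
flagged per row without aborting the scan, and monotone-likelihood
divergence is reported as non-convergence rather than returned silently.
Expression covariates are continuous per-unit z-score. Wald 95% intervals
are symmetric on the log-hazard scale by construction.

Median splits send ties at the median to the *low* group — an arbitrary
but reproducible convention, recorded here because "less or greater than
median" alone does not determine the split in the presence of ties. The
rank-sum comparison is exact by enumeration for combined $n \le 12$
without ties, otherwise the normal approximation with tie and continuity
corrections, and the method used is reported in the result.

## Problem sizes used in validation

The test-suite and acceptance-script cohorts use 60–300 genes and
250–2,000 samples, with 15–50 replicate cohorts for distributional
claims; these sizes give stable medians for every statistic checked while
keeping a full validation run in the order of a minute. Properties that
depend on the marker-to-universe ratio (the rank-competition effect
above) are validated at the 8%/6% default proportions.

## Known limitations

* The generator's four-population mixture cannot represent cell types
  whose profiles are intermediate or correlated with multiple
  compartments (no spillover structure).
* Partial Spearman residualization assumes the confounder effect is
  monotone; strongly non-monotone purity effects would leave residual
  confounding.
* The enrichment score's weighted walk is reported on its natural
  running-sum scale; scores are comparable across samples of one matrix,
  not across universes of different size.
* The survival generator's exponential baseline cannot test
  proportionality diagnostics (none are implemented; the scan assumes
  proportional hazards).
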