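---
title: "Methods and design notes for chemoMGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for chemoMGP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoMGP)
```

## The problem

A multi-gene predictor (MGP) of chemotherapy response can be trained on a
cancer cell-line panel instead of a patient cohort: sensitivity to a drug
combination is measured in vitro for each line, a regression model links
sensitivity to baseline expression, and the resulting score is applied —
blinded to outcome — to patients treated with the same drugs. chemoMGP
implements that pipeline end to end for bulk microarray data and provides
the statistics used in a blinded clinical validation. This vignette records
the model, the tunable parameters, the numerical conventions, and the design
choices made where more than one reasonable option existed.

## Dose–response sensitivity scoring

A plate holds, for one cell line, replicate surviving-cell counts at ten
serial dilutions plus untreated control wells. The survival fraction at
dose $i$ is the ratio of the arithmetic mean treated count at that dose to
the arithmetic mean control count, and the sensitivity score is

$$\mathrm{AUC} \;=\; \sum_{i=1}^{10} \mathrm{SF}_i ,$$

a plain sum over the ordinal dose indices — no trapezoid rule, no
concentration weighting. Lower AUC means greater sensitivity; the score
lives in $[0, 10 \times \max \mathrm{SF}]$ and is unitless.

Conventions worth stating:

* replicate aggregation is the arithmetic mean, with no outlier-well
  rejection;
* survival fractions above 1 (treated wells outgrowing controls at low
  doses) are retained, since clipping would change the AUC;
* control wells are plate-global, not per-dose;
* a plate whose control mean is zero is an error — we do not impute failed
  controls, because nothing in the assay model tells us how.

## Expression preprocessing

Inputs are post-summarization log2 intensity matrices (probes × samples).
Two steps, in this order:

1. **Non-specific filtering** on the *unstandardized* values: a probe is
   removed if its interquartile range across samples is below `iqr_min`
   (default 0.5 log2 units) or its median is below `median_min` (default
   `log2(100)` ≈ 6.64). Removal is strict `<`, so ties at either threshold
   are kept. A probe failing both rules is reported under low variation
   only, making the filter report a partition of the input. Quantiles use
   the linear-interpolation (type 7) convention so results are exactly
   reproducible.
2. **Per-sample standardization**: each array is centered and scaled to
   mean 0, sd 1 (denominator $n-1$) over the current probe universe.

Filtering before standardization matters: the filter criteria are on the
raw log2 scale, and standardization would destroy both.

When a patient platform carries only a subset of the training probes, the
new arrays are standardized over the *training filter universe intersected
with the new platform* and then projected (`universe = "training"`, the
default). Standardizing over the model probes only is available as
`universe = "model"`; the choice is exposed because the correct universe for
a foreign platform is genuinely underdetermined, and the two differ only
through the standardization denominator.

## The supervised principal-components model

With $y$ the AUC vector and $x_j$ the (preprocessed) expression of probe
$j$ across the panel, the feature score is the standardized univariate
regression coefficient

$$s_j \;=\; \frac{(x_j-\bar x_j)\cdot(y-\bar y)}{\lVert x_j-\bar x_j\rVert},$$

with a two-sided p-value from the univariate regression $t$-test
($n-2$ df) and Benjamini–Hochberg q-values across probes. Selection keeps
probes with $|s_j| \ge \theta$: thresholding the *absolute* score is the
supervised-PC convention and is what admits the mixture of up- and
down-regulated probes such signatures always contain.

The model is the first right-singular direction of the probe-centered
selected submatrix (samples as observations): unit-norm loadings $v$,
component scores $u_i = (x^{(i)} - \mu)\cdot v$ with $\mu$ the training
probe means, and an ordinary least-squares regression
$\hat y = \alpha + \beta u$. If $\beta < 0$ the loadings are negated, so
$\beta \ge 0$ always and a lower score always means more sensitive. With a
single selected probe the construction collapses, as it should, to the
univariate regression on that probe.

Prediction scores are therefore on the *predicted-AUC scale*. We do not
rescale them, and we deliberately do not define a responder/non-responder
cutoff — establishing one needs a large independent cohort.

**Missing probes at prediction time.** If some model probes are absent from
the new platform, the loadings and training means are restricted to the
available probes and the loadings renormalized to unit norm. Up to 50%
missing is tolerated with a loud warning; beyond that, scoring errors out.
The 50% cap is a guardrail, not a calibrated quantity.

## Threshold selection by cross-validation

Samples are split into $k = 10$ seeded folds (sizes differing by at most
one). For each fold and candidate threshold, screening and the
first-component fit are redone on the training split alone; held-out
samples are projected onto the training loadings and the squared Pearson
correlation between their component scores and their AUC values is the
fold statistic. A candidate selecting zero probes in a training split
contributes 0. The default candidate grid is 40 evenly spaced values
between the 50th and 99th percentile of the absolute feature scores.

**Why the one-standard-error rule.** The fold-mean curve is typically flat
over a wide threshold range: once the truly informative probes dominate the
first component, adding hundreds of weakly scored probes barely moves the
held-out correlation. On such a plateau the plain argmax lands essentially
at random, often at a low threshold that drags large numbers of
uninformative probes into the model without any measurable gain. We
therefore select, by default, the *largest* candidate whose fold-mean
statistic is within one fold standard error of the maximum — the same
parsimony rule used by cross-validated lasso and tree pruning. The curve
falls off sharply once the threshold starts cutting into genuinely
informative probes, which is what makes the rule safe. `rule = "max"`
restores the plain argmax for comparison.

The CV objective itself (mean held-out squared correlation) is a choice;
likelihood-ratio objectives from the supervised-PC literature would also be
defensible but are not implemented.

## Validation statistics

* **AU-ROC** is computed by rank (Mann–Whitney), ties counting ½, with a
  `positive_low` flag so that a pCR patient "wins" a pair when its score is
  *lower*. It is invariant under strictly increasing score transforms.
* **Confidence intervals** use the DeLong placement-value variance,
  $\widehat{\mathrm{var}} = s^2_{10}/m + s^2_{01}/n$, with a Wald interval
  clipped to $[0,1]$. Zero placement variance (e.g. perfect separation)
  collapses the interval to the point estimate and sets a `degenerate`
  flag rather than fabricating width.
* **Wilcoxon rank-sum** p-values are exact (enumeration) when the combined
  sample size is ≤ 12 with no ties, otherwise the normal approximation with
  tie and continuity corrections.
* **Odds ratios**: for a 2×2 table, the closed form $ad/bc$ with the Wald
  interval $\exp(\ln \mathrm{OR} \pm z_{1-\alpha/2}\sqrt{1/a+1/b+1/c+1/d})$;
  zero cells are an error (no continuity correction), because a silent 0.5
  correction changes published-scale numbers. $z$ is `qnorm(0.975)`
  = 1.959964, not 1.96 — the difference is visible at two printed decimals
  for wide intervals.
* **Logistic regressions** use the binomial GLM maximum-likelihood fit.
  Covariate coding: ER/PR/HER2 positive = 1; nodal N1–N3 = 1 vs N0 = 0;
  grade 3 = 1 vs 1&2 = 0; tumor stage T as ordinal 1–4 (the natural default
  where no coding is dictated); age and score continuous. Unknown values are
  dropped complete-case, per analysis, with the dropped count reported.
  Non-convergence or separation (exploding coefficients or standard errors)
  is flagged in the output rather than silently reported.
* **Enrichment** is overlap-based: the observed overlap of the selected
  genes with each set is compared against draws of the same number of genes
  uniformly without replacement from the universe, with the add-one
  permutation p-value $(1 + \#\{\text{overlap} \ge \text{obs}\})/(1 + B)$
  — never exactly zero — and BH q-values across sets (enriched at
  q < 0.1). Gene-label resampling is the simplest permutation null for a
  fixed selected list; the permutation p-value converges to the
  hypergeometric tail, which the tests exploit as an oracle.

The ER-stratified ROC analyses are run within the largest treatment arm,
with unknown-ER patients excluded from both strata. Scores are computed and
persisted *before* the clinical table is read (`run_validate()` enforces
the ordering), preserving the blinding contract.

## Synthetic data: what it emulates, and what it does not

The generators exist so that every stage has testable ground truth.

**Cell-line panel** (`panel_config()`): each line has a latent sensitivity
$u_i \sim N(0,1)$; its AUC is `auc_mean + auc_sd·u + ε`,
$\varepsilon \sim N(0, \texttt{auc\_noise\_sd})$, truncated at 0; each of
`n_informative` planted probes follows `baseline_j + effect_beta·u + noise`;
the remaining probes are independent noise around baselines drawn to
straddle the median-filter threshold, so filtering genuinely removes about
half of them. Defaults — 42 lines, 2000 probes, 50 informative,
`effect_beta` = 1, `noise_sd` = 0.5 log2 units, AUC 5 ± 1.5 — put the
planted-probe correlation with AUC near
$\beta \sigma_y / \sqrt{(\beta^2+\sigma^2)(\sigma_y^2+\tau^2)} \approx 0.89$,
a strong but not degenerate signal for a 42-sample panel.

**Dose–response plates** (`generate_dose_response_plate()`): a monotone
logistic kill curve whose midpoint is found by bisection so the ten
survival fractions sum exactly to the target AUC, then integer counts with
multiplicative lognormal noise (`noise_cv` = 0.05) around `SF ×
control_mean`. The control mean dominates the AUC error budget — it divides
every well — so plates carry a full 16-well control column (as on a
384-well layout) against triplicate treated wells. Under these defaults the
recovered AUC is within 0.3 of the target with probability ≥ 0.95, which
the test suite checks by Monte Carlo.

**Patient cohort** (`cohort_config()`): fresh latents $u$, expression from
the same generative law restricted to a random 90% of probes (emulating a
smaller patient platform inside the training platform), and
$\Pr(\mathrm{pCR}) = \mathrm{logistic}(-0.7 - 2.5\,u)$. Those coefficients
were chosen by design calculation: they give a mean pCR fraction near 0.4
(matching a neoadjuvant trial arm of 25 pCR / 41 RD) and a latent-score
AU-ROC near 0.90 — the strong-signal regime in which a well-built pipeline
should detect the association at $n = 66$. Clinical covariates are drawn
from trial-like categorical distributions *independently* of $u$, so in
univariate logistic tables only the score should carry signal. HER2 status
is coupled to the trastuzumab arm for realism, but still independent of
$u$.

What the generators do **not** emulate: probe-level summarization noise,
batch effects, correlated probe blocks (each probe's noise is independent),
heteroscedasticity, platform-specific probe behavior, or any dependence of
clinical covariates on tumor biology. Passing tests therefore demonstrate
algorithmic correctness and calibration under the stated model, not
real-data performance; on real arrays the informative-probe signal is
weaker and correlated, and recall at the cross-validated threshold will be
correspondingly lower.

The DeLong coverage simulation uses a separate binormal score model
(positives $N(-\delta,1)$, negatives $N(0,1)$), because there the true AUC
is available in closed form, $\Phi(\delta/\sqrt 2)$, which a coverage claim
needs.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on 20 seeded
default panels (42 × 2000) with 10-fold CV, validate 20 matched 66-patient
cohorts, simulate 1000 cohorts for DeLong coverage and 200 plates for AUC
recovery — sizes at which every stochastic check is stable across seeds
while the whole suite stays fast. All generators and the CV fold partition
are pure functions of (config, seed); library code saves and restores the
caller's RNG state. Model JSON is written with 17 significant digits so a
serialized model reproduces scores bit-for-bit.

## Known limitations

* Only the first principal component is used; multi-component supervised-PC
  variants are out of scope.
* Prediction scores are on the predicted-AUC scale of the training panel;
  no cross-cohort renormalization is attempted.
* The probe→gene mapping for enrichment takes gene symbols as given;
  many-to-one probe collapses are the caller's responsibility.
* Raw probe-level summarization (CEL-file processing) is upstream of this
  package; inputs must already be log2 summarized intensities.
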