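---
title: "Methods: semi-supervised RPMM classification of CpG island methylation"
author: "ssRPMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-supervised RPMM classification of CpG island methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssRPMM)
```

## The problem and the model

DNA methylation measured in oral rinse (or other easily collected) samples
carries a signature of oral and pharyngeal carcinoma. On Illumina
450K-style arrays, methylation at each CpG is summarized as a beta value
$\beta = \max(\mathrm{Cy5}, 0) / (|\mathrm{Cy3}| + |\mathrm{Cy5}| + 100)$,
a proportion in $[0, 1)$ formed from the methylated (Cy5) and unmethylated
(Cy3) channel intensities with an offset of 100 that regularizes
low-intensity probes. ssRPMM builds a case/control classifier from such
data in two supervised-then-unsupervised stages:

1. **Outcome-guided feature ranking.** Probe betas are filtered (SNP
   probes; probes with detection $p > 0.01$ in any sample), averaged over
   annotated autosomal CpG islands covered by at least three probes, and
   logit-transformed to M-values, $M = \log_2 \beta / (1 - \beta)$. One
   linear mixed-effects model per island,
   $M \sim \mathrm{case} + \mathrm{age} + \mathrm{sex} +
   \mathrm{pack\ years} + \mathrm{alcohol} + (1 \mid \mathrm{batch})$,
   is fitted by REML on the training set, and islands are ranked by the
   absolute Wald t-statistic of the case indicator.

2. **Recursively partitioned beta-mixture clustering (RPMM).** On the raw
   beta scale, subjects are clustered by a hierarchical mixture model whose
   class-conditional likelihood is a product of independent beta densities
   per island. Each node of the binary tree is tentatively split by a
   two-component EM; the split is kept iff it lowers the node's BIC.
   Classes are named by their branch path (root `r`, then `L`/`R`), so
   `rRL` is the leaf reached by a right then a left branch. The number of
   islands $M$ handed to the clustering is chosen by nested
   cross-validation that maximizes the held-out association (chi-square)
   between class label and case status. Held-out samples are assigned to
   classes by an empirical Bayes posterior: class weight times
   class-conditional likelihood, normalized.

Performance is reported the way screening studies report it: sensitivity
and specificity of the case-heavy classes, exact and logistic odds ratios,
and ROC/AUC with a DeLong confidence interval; classifier islands can be
checked in paired tumor/normal data with Wilcoxon signed-rank tests under
Benjamini–Hochberg FDR control.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `detectionThreshold` | 0.01 | probe detection p cutoff; a probe failing in any sample is dropped array-wide |
| `minProbes` | 3 | minimum probes per retained island |
| `epsilon` | 1e-6 | clamp bound before the logit (M-value) transform |
| `trainFraction` | 2/3 | stratified train share (2:1 split, floor per stratum) |
| `mGrid` | 2..min(50, islands) | candidate island counts for nested CV |
| `nFolds` | 10 | stratified CV folds |
| `minClassSize` | 5 | minimum expected members per RPMM class |
| `maxDepth` | 6 | maximum RPMM tree depth |
| `positiveThreshold` | 0.8 | training case fraction defining a case-heavy class |
| `qThreshold` | 0.05 | FDR cutoff in the paired validation |

## Numerical choices

* **Beta likelihoods.** Values are clamped to $[10^{-6}, 1 - 10^{-6}]$
  before every likelihood evaluation, so boundary betas stay finite.
  Per-feature beta shapes are fitted by weighted maximum likelihood:
  method-of-moments start ($a = m(m(1-m)/v - 1)$, $b = (1-m)(m(1-m)/v-1)$),
  damped Newton refinement with step-halving, so the refined
  log-likelihood never falls below the moment fit's. Moments are taken on
  the raw values so that data more dispersed than any beta law
  ($v \ge m(1-m)$, e.g. a two-point mass at 0 and 1) are detected and fall
  back to a clipped moment fit with unit concentration $a + b = 2$.
* **EM.** Initialization is deterministic: a soft split (0.8/0.2) on the
  sign of the first principal direction of the weighted, centered
  logit-scale data, with the direction's sign fixed by its
  largest-magnitude loading — fits are therefore reproducible and
  invariant to sample order. M-steps keep the previous parameters whenever
  a refit would lower that component's weighted likelihood (generalized
  EM), making the log-likelihood provably non-decreasing; convergence is
  declared at a relative change below $10^{-8}$ (cap 1000 iterations).
* **Split decision.** BIC with the node's effective sample size
  $n_\mathrm{eff} = \sum_i w_i$ (fuzzy weights), $k = 2p$ parameters for
  one class and $4p + 1$ for two. Recursion is fuzzy — children inherit
  parent weight times membership posterior — which matches the mixture
  framing and stabilizes small classes relative to hard partitioning.
* **Ties.** Ranking ties break lexicographically by island id; posterior
  ties go to the lexicographically smallest class name; CV objective ties
  go to the smallest $M$ (parsimony).
* **Degenerate inputs.** Constant islands yield $t = 0$ with a flag;
  single-batch designs drop the random intercept (equivalently, the
  variance is pinned at zero) and use OLS; mixed-model failures fall back
  to the fixed-effects fit with a flag; perfect separation in logistic
  models is flagged, not fatal.
* **Signed-rank test.** Zero differences are dropped (Wilcoxon's
  convention); the exact null (via `psignrank`) is used for at most 25
  untied non-zero pairs, otherwise the normal approximation with
  continuity and tie corrections — so a 34-pair tumor/normal panel uses
  the approximation. Median differences are computed over all pairs,
  zeros included; positive values denote tumor hypermethylation.
* **Odds ratios.** `fisherExactOR()` reports the conditional MLE with the
  exact-test interval; `logisticModel()` reports the unconditional MLE
  with Wald or profile-likelihood intervals. The two disagree for sparse
  tables (the conditional estimate is pulled toward 1 and the exact
  interval is wider); both are reported because published crude ORs for
  sparse 2x2 tables are usually the logistic/profile pair.

## What the synthetic generator emulates — and what it does not

`simulateCohort()` plants the structure the analysis assumes: latent
methylation classes with class-specific case probabilities (case-heavy
classes), a small set of informative islands whose class-conditional mean
betas differ by a configurable delta, beta-distributed island values with
a common concentration, probe-level scatter, covariates, and a batch label
injected as an additive M-scale shift (so the ranking stage's random
intercept has something to absorb).

Default study conditions (fixed once, used by the tests and the
acceptance script): 152 cases and 71 controls (a post-QC cohort of 223);
four latent classes with weights (.30, .25, .25, .20) and case
probabilities (.97, .92, .35, .15), giving two case-heavy classes and an
overall case fraction near 0.64; 300 islands with 20 informative, deltas
alternating in sign with magnitudes 0.10–0.30 (the range reported for
validated classifier islands); island beta concentration 50 (sd about
0.07 at $\beta = 0.5$); 4 probes per island with scatter sd 0.02; three
processing batches with an M-scale shift of 0.15. Case status is drawn
per sample from its class's case probability, so realized case counts
vary around the configured totals.

Two structural choices are worth knowing. First, with the default pattern
all informative islands contrast the case-heavy block against the rest,
so the block-vs-rest mean gap equals the configured delta exactly — the
price is that classes within the block share a methylation profile. Tests
that need more than two distinguishable planted profiles pass
`classPatterns`, a 0/1 islands-x-classes matrix saying which classes are
shifted on each island. Second, covariates are independent of class and
status by default (an `ageCaseShift` knob introduces confounding when
wanted), so passing tests here say nothing about confounding structures
in real cohorts. The generator also does not emulate probe type I/II
chemistry, color-channel effects, raw intensities, cell-type mixture, or
the correlation of neighboring islands — conclusions from synthetic runs
are about the algorithm, not about any particular tissue.

For the nested-CV check we deliberately use a weak-moderate regime (10
informative islands among 300, delta magnitudes 0.08–0.20, concentration
30, 5 folds, grid {2, 3, 5, 8, 12, 18, 25, 35, 50}): with strong effects
even two islands separate the classes, the CV objective plateaus, and the
parsimony tie-break always selects the grid minimum — weak effects are
the regime where the number of islands genuinely matters. End-to-end
discrimination checks use the default cohort with a fixed $M = 20$
(number of informative islands) for speed; null-cohort checks set all
class case probabilities equal and average the held-out AUC over five
seeds. Problem sizes throughout (a few hundred islands, a couple of
hundred samples, five folds) are chosen so the whole suite runs
comfortably on a laptop while keeping every statistical property at
cohort-realistic scale.

## A worked run

```{r pipeline, eval = FALSE}
summary <- runPipeline(list(
    simulate = list(),          # default synthetic cohort
    mGrid = c(5, 10, 15, 20, 25, 30), nFolds = 5, seed = 1,
    outDir = "run1"))
summary$selected_m; summary$n_classes; summary$auc
```

The run directory holds the sample sheet with its split, the ranking TSV,
the CV trace, the classifier JSON (round-trip stable), per-sample test
posteriors, ROC points, a summary JSON, and a manifest with parameters,
seed and artifact hashes; re-running the identical configuration
reproduces the artifacts byte for byte.

## Known limitations

* The RPMM assumes conditionally independent beta-distributed features;
  strongly correlated islands can inflate the apparent class count.
* The CV objective (held-out class-vs-case chi-square) targets binary
  outcomes only.
* The conditional-MLE and logistic odds ratios legitimately differ for
  sparse tables; neither is "the" crude OR without naming the procedure.
* Probe-level modelling (type I/II chemistry, normalization, batch
  correction of raw intensities) is upstream of this package: inputs are
  assumed to be already-normalized beta matrices, with residual batch
  handled as a random effect in the ranking stage.
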