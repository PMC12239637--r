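---
title: "Methods: tissue-specificity classification and pollen-tube statistics"
author: "pollenTau"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-specificity classification and pollen-tube statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenTau)
```

# Scope and model

pollenTau compares gene expression across three tissues — leaf, pollen, and
style — in two *Solanum* species, a selfing one (`SL`) and an outcrossing
one (`SP`), and pairs the expression analysis with statistics for
pollen-tube growth assays. The unit of expression is TPM (transcripts per
million), computed from a counts matrix and gene lengths; the unit of the
phenotype analysis is the biological replicate (a pollen donor).

The data model is a `SummarizedExperiment` stack: `TissueCounts` holds raw
integer counts with gene lengths and a validated sample design (species,
tissue, subtissue, biological replicate); `TpmExperiment` holds TPM;
`TpmProfileSet` holds per-species tissue-mean and replicate-mean profiles
after subtissue collapsing.

# TPM and profile construction

For gene $g$ with length $L_g$ (bp) and count $c_{gs}$ in sample $s$, the
length-normalized rate is $r_{gs} = c_{gs} / (L_g / 1000)$ and
$\mathrm{TPM}_{gs} = 10^6 \, r_{gs} / \sum_g r_{gs}$. Columns therefore sum
to $10^6$ exactly (all-zero samples stay zero). Gene lengths come either
from the counts file or from a GFF3 via union-exon lengths: exons are
resolved to their parent gene through the `Parent` chain, overlapping exons
are merged, and the length is the width sum of the merged set. Exonless
genes fall back to the annotated span, with a warning.

Leaf samples arrive as 7 subtissue sections and pollen as 2 states
(ungerminated, germinated) per biological replicate. `collapseSubtissues()`
averages subtissues within each (species, tissue, replicate) before any
inference, so each tissue contributes one value per replicate.
`tissueProfiles()` then averages replicates into tissue means per species.

The expressed universe is every gene whose tissue mean reaches at least
2 TPM in any species and tissue (inclusive threshold; `filterExpressed()`).

# The tau index and classification

For tissue means $x_1, \dots, x_N$ ($N = 3$ here),

$$\tau = \frac{\sum_{i=1}^{N} (1 - \hat{x}_i)}{N - 1},
\qquad \hat{x}_i = \frac{x_i}{\max_i x_i}.$$

$\tau$ is 0 for uniform expression, 1 for single-tissue expression, and is
scale invariant. Per species, each expressed gene gets a focal tissue (the
tissue of maximal mean; exact ties resolve in the fixed order leaf, pollen,
style) and a class:

* **biased** — $\tau \ge 0.7$;
* **specific** — biased, focal mean $\ge 2$ TPM, and every other tissue
  mean below the detection floor of 0.1 TPM (the practical form of
  $\tau = 1$ under TPM arithmetic); specific genes are a subset of biased
  genes;
* **unbiased** otherwise; genes with an all-zero profile in one species are
  flagged `unexpressed_in_species` there.

All three thresholds (2 TPM expression, 0.7 tau, 0.1 TPM floor) are
arguments, and `thresholdSensitivity()` re-runs the classification over a
tau grid to show which counts depend on the 0.7 convention.

A gene is **reproductive-specific** when it is in the universe, its leaf
mean is below 2 TPM in *both* species, and its pollen and/or style mean
reaches 2 TPM in at least one species.

For the union of genes pollen-biased in either species,
`compareSecondaryStyleExpression()` asks whether the gene also has
*secondary* expression in the style (style mean $\ge 2$ TPM in either
species), which species expresses it higher there, and whether it is absent
from `SL` styles (below the 0.1 TPM floor). The direction counts partition
the secondary total, which is the identity `domainDirectionCounts()`
checks.

# Differential expression

Size factors use the median-of-ratios estimator: over genes with nonzero
counts in every sample, the reference is the per-gene geometric mean, and a
sample's factor is the median of its count-to-reference ratios
(equivalently $\exp(\mathrm{median}(\log \text{ratios}))$). This matches
`DESeq2::estimateSizeFactorsForMatrix()`, which the test suite uses as an
oracle.

The per-gene species contrast is deliberately a *stand-in*, not a
negative-binomial GLM: a Welch two-sample $t$ on $\log_2(\text{normalized
count} + 1)$, adjusted by Benjamini–Hochberg within each contrast family
(pollen, style). This is not equivalent to DESeq2's Wald test — it ignores
the mean–variance relationship of counts and is conservative at three
replicates — but it is fully self-contained, exactly reproducible, and its
null behavior is verified by simulation in the tests. Results carry
`log2fc` defined as $\log_2((\bar{x}_{SP}+1)/(\bar{x}_{SL}+1))$ on
normalized counts.

The Benjamini–Hochberg adjustment is written closed-form (sort, step-up
cumulative minimum, map back) and is tested against both
`stats::p.adjust(method = "BH")` and a brute-force evaluation of the
step-up definition.

# Gene families

PME (pectin methylesterase) and PMEI (its inhibitor) membership is curated
by case-insensitive fixed-substring matching of annotation descriptions.
Inhibitor patterns take precedence: a description containing
"pectin methylesterase inhibitor" is a PMEI even though it also contains a
PME substring. `reproductiveFamilySubset()` intersects assignments with
the reproductive-specificity flag; `familyExpressionReport()` adds
per-gene tissue means, contrast directions, and a between-species Welch
test on $\log_{10}(\mathrm{TPM}+1)$ group means.

# Phenotype statistics

`summarizeAssays()` reduces raw assay records to one row per pollen donor.
In vitro: germination rate, mean pollen diameter, and growth rate = mean
tube length (µm) / elapsed hours (3 h cultures by default). In vivo: the
mean of the 5 longest tubes (fewer with a warning) over the record's own
elapsed time (5–7 h window), style length, and the proportion of the style
traversed. Technical replicates are averaged within donors before any
test, so sample sizes in tests are donor counts.

`speciesComparisonReport()` runs Welch two-sample tests (direction
SP − SL) on the six panel metrics plus a two-sided variance-ratio $F$ test
on in vitro growth rates (SL variance over SP). Welch rather than
pooled-variance is the default because the in vitro rates are expected to
have unequal variances between species; a `pooled = TRUE` flag restores
the classical test. Degenerate inputs follow fixed contracts (zero
variance in both groups: $p = 1$ for equal means, $p = 0$ otherwise;
one-way ANOVA with zero within-group variance: $F = \infty, p = 0$ for any
between-group spread).

## Power note on the variance-ratio test

At 5 donors per species, a planted 4-fold variance ratio gives the
two-sided $F$ test only ~25% power ($F_{4,4}$ quantiles are extreme), so
no test asserts detection at that size. The property "a 4× ratio is
detected in ≥ 80% of simulations" holds at 20 donors per group
(theoretical power ≈ 0.81), and that is the size at which the test suite
verifies it. The sign-reversal panel (faster in vitro growth in SL, faster
in vivo growth in SP) does reach ≥ 0.8 power at the realistic 5-donor
design, which simulation over 200 seeds confirms.

# Synthetic data

`generateExpression()` plants a class for every gene (leaf/pollen/style ×
specific/biased, unbiased, silent), per-species secondary-style directions
for chosen pollen-biased genes, and PME/PMEI memberships with matchable
description strings. Class profiles are specified as relative levels
(focal:nonfocal ratio 10:1 by default) and then renormalized per species ×
tissue to sum to $10^6$, so the *expected TPM of every gene is exact by
construction* and stored in the truth object. Expected TPM becomes an
expected count via gene length (log-uniform in [500, 5000] bp) and library
size (varying 2-fold across samples), and counts are drawn negative
binomial with variance $\mu + \alpha\mu^2$; $\alpha = 0$ degenerates to
rounded means. The generator refuses infeasible configurations: before
simulating, it classifies the noiseless expected profiles and errors if
any planted label would not be recovered even without noise.

What the generator does **not** emulate: isoform structure and mapping
ambiguity, GC or length biases beyond the TPM length term, correlated
genes or batch structure, outlier samples, and annotation errors. It is a
verification instrument for the pipeline's statistical logic, not a
biological simulator. Problem sizes used in tests (hundreds to 2,000
genes, 3 replicates) are the package's own choice, set to keep the suite
fast while leaving every code path exercised.

`generatePhenotypes()` plants species growth-rate means with normal
per-donor effects and residual noise; with all standard deviations zero,
every donor rate equals its planted mean exactly. `recoveryReport()`
scores classification accuracy, direction confusion, and family
recall/precision against the truth.

# Numerical choices

* Reported proportions round half *up* at 3 decimals (`roundHalfUp()`),
  avoiding banker's rounding so printed ratios match hand arithmetic.
* Result tables are written with `writeResultTable()`: rows sorted by the
  first column, doubles at 6 significant digits, so outputs are
  byte-deterministic across runs; the run manifest records MD5 checksums,
  thresholds, and the seed, and contains no timestamps.
* All RNG uses the Mersenne-Twister generator with explicit seeds.
* Closed-form statistics (Welch $t$ with Welch–Satterthwaite df, $F$
  ratio, one-way ANOVA, BH) are cross-checked in the test suite against
  `stats::t.test()`, `stats::var.test()`, `anova(lm())`, and
  `stats::p.adjust()`.

# Limitations

The species contrast is a stand-in for a count-model test and should not
be interpreted as a DESeq2 replacement; tau on three tissues is coarse
(many profiles share a tau value); the 2 TPM / 0.7 / 0.1 thresholds are
conventions whose sensitivity should be reported alongside results; and
family curation by description keywords inherits whatever errors the
annotation contains.
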