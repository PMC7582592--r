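---
title: "Models and methods behind aquamiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aquamiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquamiR)
```

## The analytical problem

Secreted microRNAs in small-volume biofluids — aqueous humor sampled by
paracentesis, plasma — are commonly profiled by RT-qPCR arrays that
report one cycle-threshold (Ct) value per miRNA per sample.  Ct is
approximately `-log2` of input abundance plus an assay constant, so
differences of Ct values are log2 fold changes.  Three features of such
data drive the design of every stage in this package:

1. **Censoring.**  Weak signals fail to amplify ("Undetermined") or
   cross threshold so late that the value is unreliable.  A detection
   limit (Ct 35 by convention) separates usable from unusable wells,
   and missingness is informative — low-abundance miRNAs drop out
   first.
2. **Per-sample scale shifts.**  Input amount, extraction yield and
   pre-amplification efficiency shift all of a sample's Ct values by a
   roughly common additive offset.  Normalization exists to remove this
   nuisance term.
3. **No universally stable reference.**  Unlike tissue mRNA assays
   there is no agreed housekeeping miRNA for biofluids, so the
   reference set must be chosen from the data, and conclusions should
   be shown to be robust to the normalization choice.

The package implements the complete workflow: detection filtering,
data-driven reference selection, dual-strategy normalization, consensus
differential expression, single-assay validation, and the arithmetic of
pathway overrepresentation summaries — together with a synthetic data
generator that makes the whole chain testable against planted ground
truth.

## Detection filtering

A miRNA is *detected in a group* when its Ct is present and at most the
threshold (default 35.0) in at least `ceiling(0.8 * n_group)` of the
group's samples, and *reliably detected* when this holds in at least
one group.  At the classic profiling size of five subjects per group
the rule is the familiar "at least 4 of 5"; the fractional form extends
it to other cohort sizes (8 gives 7, 12 gives 10) and an absolute
override is available.  A missing Ct can never satisfy the criterion —
the only consistent reading when missingness means non-amplification.
Detection is computed on profiling-stage samples only by default, so
later validation samples cannot redefine the detected set.  For
three-group designs the detected set is partitioned into the seven
regions of a Venn diagram by each miRNA's detection signature.

## Reference selection by combined stability

Candidates are the miRNAs with a complete row of observations: an
endogenous control must be measurable in every sample.  Three
complementary stability scores are computed on the candidates, each on
the Ct (log2) scale, each oriented so that smaller is more stable.

**geNorm M.**  For candidates $j, k$ the pairwise variation
$V_{jk} = \mathrm{sd}_\text{samples}(Ct_j - Ct_k)$ is the standard
deviation of a log ratio; $M_j$ is the mean of $V_{jk}$ over all other
candidates.  Because it is built on within-sample differences, $M$ is
exactly invariant to per-sample additive offsets.  The package computes
the direct (single-pass) $M$; the classic iterative worst-gene
elimination is available separately (`genorm_rank_stepwise()`) but does
not feed the combined score, which is defined on the one-shot values.

**Model-based stability (NormFinder type).**  With candidates
$i = 1..k$, groups $g = 1..G$ of sizes $n_g$, and sample-centred data
$z_{igj} = y_{igj} - \bar{y}_{\cdot gj}$ (centring removes the
per-sample offset):

* within each group, the sample variance $v_{ig}$ of $z_{igj}$
  estimates a mixture of the candidate's own residual variance and the
  shared centring term; the bias-corrected candidate variance is
  $\hat\sigma^2_{ig} = \max\!\big(0,\; (v_{ig} - \bar{v}_{g}/(k-1))
  \cdot k/(k-2)\big)$ (negative method-of-moments estimates are clamped
  to zero);
* the group deviation $d_{ig} = \bar{z}_{ig} - \frac1G\sum_h
  \bar{z}_{ih}$ measures systematic intergroup difference; its true
  variance $\gamma^2$ is estimated by moments,
  $\hat\gamma^2 = \max\!\big(0, \sum_{ig} d_{ig}^2 / ((k-1)(G-1)) -
  \overline{\hat\sigma^2_{ig}/n_g}\big)$, and each deviation is shrunk
  by its sampling variance,
  $\tilde d_{ig} = d_{ig}\,\hat\gamma^2 / (\hat\gamma^2 +
  \hat\sigma^2_{ig}/n_g)$;
* the stability value is
  $\rho_i = \frac1G \sum_g \Big( |\tilde d_{ig}| +
  \sqrt{\widetilde{\mathrm{var}}(\tilde d_{ig}) +
  \hat\sigma^2_{ig}/n_g} \Big)$, i.e. the shrunken systematic bias plus
  the standard error of the candidate's group-level expression.

The final combination step is a design decision of this package: it
keeps intragroup variance informative even when $\hat\gamma^2 = 0$,
where a pure shrinkage formula would collapse every candidate to zero
and lose the ranking.  A no-group variant (`grouped = FALSE`) returns
the bias-corrected residual SD alone.

**Scaled CV.**  $CV_j = \mathrm{sd}_j / \mathrm{mean}_j$ of raw Ct
across samples, scaled by the summed CV of all candidates so the scores
form a partition of 1.  The phrase "scaled by the sum of all CVs"
admits two readings (sum over candidates or over samples); the package
sums over candidates, since a per-sample CV across different miRNAs is
not a property of any single candidate.  Unlike $M$, this score *does*
respond to per-sample offsets — it rewards candidates whose absolute
level barely moves; the test suite asserts both sensitivities in
opposite directions, deliberately.

**Summarized stability score.**  $SSS_j = \sqrt{M_j^2 + \rho_j^2 +
CV^{score\,2}_j}$, the Euclidean distance of the score triple from the
origin.  Since $M$ is already an average over pairs, it enters as-is.
Candidates are ranked by ascending SSS with lexicographic id
tie-breaking for determinism, and the top `k` (default 3) become the
reference set.

## Normalization and fold changes

Two strategies produce $\Delta Ct$ matrices:

* **global mean** — $\Delta Ct_{ij} = Ct_{ij} - \overline{Ct}_{\cdot j}$
  over a basis set; the basis defaults to the reliably-detected set
  (intersected with what is observed in each sample) because averaging
  over unreliable near-limit wells would inject censoring bias;
* **reference** — the normalizer is the arithmetic mean of the
  reference miRNAs' Ct, i.e. the geometric mean of their linear
  quantities, the standard multi-housekeeper aggregate.

Missing target Ct propagates to missing $\Delta Ct$; nothing is
imputed.  Relative expression is $2^{-\Delta Ct}$; between groups,
$\Delta\Delta Ct$ is the difference of group means of $\Delta Ct$ and
the fold change $2^{-\Delta\Delta Ct}$ is reported as a positive ratio
with a direction label ("down" below 1), which makes
$fc(A,B)\,fc(B,A) = 1$ exact.  In the offsets-only no-noise limit the
two strategies give identical $\Delta\Delta Ct$ — a property the test
suite checks at `1e-9`.

## Differential expression

**Profiling stage.**  For each pairwise group comparison and each
strategy, a two-sided pooled-variance Student's t-test is applied to
$\Delta Ct$ ("Student's t" is read as the classic equal-variance form;
Welch is not the default).  A miRNA is significant under a strategy
when its strategy-specific fold change passes the 2.5-fold gate in
either direction *and* raw $p \le 0.05$; the *consensus* call requires
both strategies to agree, including in direction.  No multiple-testing
correction gates the calls — the workflow this implements uses raw
p-values with the fold gate as the practical error control — but
Benjamini-Hochberg columns are emitted for transparency.  miRNAs with
fewer than two $\Delta Ct$ values in either group are flagged
not-evaluable rather than dropped.

**Validation stage.**  Promoted candidates are re-tested in
single-assay data with the two-sided Mann-Whitney U test on
$2^{-\Delta Ct}$ (exact distribution when the combined sample size is
at most 20 with no ties, tie-corrected normal approximation otherwise;
all-identical input returns p = 1 by convention).  A comparison is
validated when the observed direction matches the profiling direction
and $p \le \alpha$; a miRNA is validated when at least one of its
comparisons confirms and none is significant in the opposite
direction.  Plasma testing is gated on the AH-validated set, with the
two plasma normalizers aggregated by arithmetic mean; the association
between compartments is summarized by Spearman rank correlation
(at least four complete pairs; the statistic for this check is a
package choice, as rank-based association is the natural companion of
the Mann-Whitney calls).

## Overrepresentation arithmetic

The enrichment module consumes a counts table the user exports from an
annotation service — it never queries one, because live databases
change and make results irreproducible.  Gene percentage is
$100\,k/N$ rounded half-up (matching how printed tables round); fold
enrichment is $(k/N)/(K/M)$; the p-value is the upper hypergeometric
tail $P(X \ge k)$, with an optional conservative EASE-style variant
(testing $k-1$) behind a flag.  Printed "Fisher exact" columns of
third-party tables typically reflect internal variants and unprinted
universe counts, so the package's p-values are verified against an
exhaustive pmf-summation oracle rather than against any published
table.

## The synthetic data generator

`generate_ct_dataset()` draws
$Ct_{ij} = b_i + o_j + s_{g(j),i} + \varepsilon_{ij}$ with per-miRNA
baselines $b_i \sim U(22, 34)$ Ct, per-sample offsets
$o_j \sim N(0, 0.5^2)$ Ct, planted group shifts $s$, and technical
noise $\varepsilon_{ij} \sim N(0, \sigma_i^2)$ with $\sigma_i = 0.3$ Ct
for ordinary miRNAs and $0.05$ Ct for the three planted stable miRNAs.
Wells with true Ct above the detection limit (35) are censored
deterministically, and wells within 1 Ct below it drop out with
probability 0.2 — a simple account of the noisy boundary between
amplified and lost.  Defaults mirror the profiling design the package
targets: 378 miRNAs, three groups of five; the full-cohort single-assay
generator uses 10/8/12.  Two defaults deserve justification:

* the offset SD of 0.5 Ct is large enough that unnormalized group
  comparisons visibly fail, which is exactly what makes the
  normalization stages testable;
* planted stable miRNAs draw baselines from 22-28 Ct and planted
  shifted miRNAs from 22-30 Ct (falling back to the configured range
  when it lies entirely above these), emulating the empirical fact
  that usable endogenous controls and validated candidates are
  abundant species well clear of the detection limit.  Positive shifts
  raise Ct, i.e. lower expression: a planted 3-fold decrease is
  `+log2(3)` Ct.

The generator requires an explicit seed, restores the caller's RNG
state, and is bit-reproducible.  What it deliberately does **not**
emulate: plate/batch layout effects, amplification-efficiency
differences between assays, heavy-tailed or correlated noise across
miRNAs, hemolysis artifacts in plasma.  Passing the recovery tests
therefore demonstrates the pipeline's correctness under its own model
assumptions, not robustness to every failure mode of real arrays.

```{r generator-demo}
ds <- generate_ct_dataset(synthetic_spec(
  seed = 1, de_plan = de_plan(n = 8, group = "DME", shift_ct = log2(3))))
det <- detect_flags(ds$ct, ds$sheet)
stab <- stability_table(ds$ct, ds$sheet)
refs <- select_references(stab, 3)
identical(sort(refs), sort(ds$truth$stable))
```

## Numerical and design choices

* **Tie-breaks** in the SSS ranking (and the stepwise geNorm order) are
  lexicographic on miRNA id, making every ranking deterministic.
* **Degenerate tests**: identical constant groups give t-test p = 1;
  all-identical Mann-Whitney input gives p = 1; a zero pooled variance
  with a non-zero mean difference gives p = 0.
* **Negative variance estimates** in the model-based stability are
  clamped at zero (method-of-moments estimators go negative in finite
  samples); the intergroup variance estimate is clamped likewise.
* **On-disk round-tripping** writes each Ct with the shortest decimal
  representation that parses back to the identical double, so
  write-then-read is the identity; missing wells are written as `NA`
  and the marker set `{"Undetermined", "NA", ""}` is configurable on
  input.  Values above the detection limit are *not* converted to
  missing at the I/O layer — detection filtering owns that decision.
* **Exact/approximate switch** for the Mann-Whitney test sits at a
  combined n of 20, the conventional boundary; mid-p corrections are
  not used.
* **Identifier handling** is case-sensitive throughout: miRNA
  nomenclature distinguishes arms and close family members by suffix
  and case.

## Verification strategy and problem sizes

Every statistical kernel is tested against an independent oracle:
geNorm against a brute-force double loop over pairs; the model-based
stability against a frozen long-hand recomputation on a committed
fixture; the Mann-Whitney p against full rank-assignment enumeration
for all sample sizes up to 7 + 7; the hypergeometric tail against
explicit pmf summation; the vectorised t against `stats::t.test`.
Pipeline-level behavior is checked by simulation at the default study
conditions: 100 generated datasets for reference recovery (the planted
trio must sit in the SSS top 3 in at least 95), and 100 datasets with
eight planted 3-fold DME shifts for consensus recall (at least 0.90)
and per-strategy false-positive rates (within the binomial band of the
nominal 0.05; empirically near zero because of the fold gate).  These
sizes give the simulation checks stable Monte-Carlo behavior while the
whole suite stays fast.

## Known limitations

* The stability combination step reconstructs the model-based
  estimator from its published description; other implementations may
  combine the intra- and intergroup terms slightly differently, so
  absolute $\rho$ values are comparable only within a run (rankings
  are what the workflow consumes).
* Efficiency-corrected quantification (standard curves, Pfaffl-type
  models) and inter-plate calibration are out of scope; inputs are
  assumed to be already-called Ct values from a single platform.
* The consensus rule controls false positives well but inherits the
  conservatism of requiring two normalizations to agree; with few
  detected miRNAs the global mean itself becomes noisy and the
  reference strategy should be preferred.
* The enrichment module reproduces arithmetic, not annotation:
  pathway membership and universe sizes must come from the user's
  annotation export.
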