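# aquamiR

Analysis of miRNA RT-qPCR array profiles from small-volume biofluids
(aqueous humor, plasma), written for the common study design in ocular
and biomarker research: profile a few hundred miRNAs by TaqMan-style
array in a small cohort, pick endogenous reference miRNAs from the
data, call differentially expressed miRNAs robustly to the
normalization choice, then confirm candidates by single-assay RT-qPCR
in a larger cohort and in a second compartment.

Inputs are wide-format cycle-threshold (Ct) tables (miRNA rows, sample
columns, `"Undetermined"`/blank/`NA` for non-amplified wells) plus a
sample sheet assigning each sample to a group, a compartment and a
cohort stage.

## The method in brief

Ct is ~ `-log2` abundance plus an assay constant, so differences of Ct
are log2 fold changes.  The workflow is:

1. **Detection filtering** — a miRNA is reliably detected when
   Ct <= 35 in at least `ceiling(0.8 n)` subjects of at least one
   group (the classic "4 of 5" at n = 5); three-group designs get the
   seven Venn region counts.
2. **Reference selection** — candidates (complete rows only) are
   scored by geNorm *M* (mean pairwise variation
   `sd(Ct_j - Ct_k)`), a NormFinder-type model-based stability *rho*
   (shrunken intergroup deviation + intragroup SE after
   sample-centering), and a scaled coefficient of variation; the three
   scores merge into the summarized stability score
   `SSS = sqrt(M^2 + rho^2 + CVscore^2)` and the top 3 become the
   reference set.
3. **Dual normalization** — ΔCt against the global mean over the
   detected set, and against the arithmetic-mean Ct of the references.
4. **Consensus differential expression** — per comparison and per
   strategy: pooled-variance Student's t on ΔCt, fold change
   `2^-ΔΔCt`, significant when the fold change passes 2.5x in either
   direction and p <= 0.05; the consensus call requires both
   strategies to agree, direction included.
5. **Single-assay validation** — Mann-Whitney U on `2^-ΔCt` (exact for
   combined n <= 20 without ties), a call validated only when it
   confirms the profiling trend; plasma testing is gated on the
   AH-validated set.
6. **Enrichment arithmetic** — gene percentages, fold enrichment
   `(k/N)/(K/M)` and upper-tail hypergeometric p-values from a
   user-supplied counts table (no annotation service is queried).

A synthetic Ct generator with planted ground truth (stable trio,
group shifts, per-sample offsets, censoring above Ct 35) makes the
whole chain verifiable end to end; see
`vignette("aquamiR-methods")` for formulas, defaults and design
decisions.

## Worked example

```r
library(aquamiR)

spec <- synthetic_spec(seed = 42,
                       de_plan = de_plan(n = 8, group = "DME",
                                         shift_ct = log2(3)))
ds  <- generate_ct_dataset(spec)       # ct, sheet, truth
det <- detect_flags(ds$ct, ds$sheet)
det
#> Detection at Ct <= 35 (min subjects per group: CTR=4, D=4, DME=4)
#> 378 miRNAs detected in >= 1 group; per group: CTR=378, D=377, DME=378

stab <- stability_table(ds$ct, ds$sheet)
head(as.data.frame(stab), 4)
#>         mirna         M        rho    cv_score       sss rank
#> 1 syn-miR-321 0.3132488 0.04526451 0.002209353 0.3165099    1
#> 2 syn-miR-153 0.3145030 0.04836357 0.002363205 0.3182087    2
#> 3 syn-miR-049 0.3149533 0.05259329 0.002216975 0.3193220    3
#> 4 syn-miR-244 0.3430892 0.09432878 0.002155537 0.3558269    4

refs <- select_references(stab, 3)     # the planted stable trio:
sort(refs)                             # syn-miR-049, -153, -321

ct_det <- ct_matrix(unclass(ds$ct)[union(det$detected_set, refs), ])
de <- profiling_de(ct_det, ds$sheet, refs, basis = det$detected_set)
subset(as.data.frame(de), consensus)[1:3,
       c("mirna", "comparison", "fc_reference", "p_reference", "direction")]
#>           mirna comparison fc_reference p_reference direction
#> 402 syn-miR-024 DME_vs_CTR        0.390    3.91e-07      down
#> 428 syn-miR-050 DME_vs_CTR        0.303    2.19e-05      down
#> 453 syn-miR-075 DME_vs_CTR        0.329    1.72e-04      down
```

The consensus calls are the planted 3-fold DME knock-downs: fold
changes cluster around the planted `2^-log2(3) = 0.33` with the
expected `down` direction, and the three selected references are
exactly the planted stable trio.  Enrichment arithmetic on exported
counts works the same way:

```r
gene_percentage(9, 1613)            # 0.6   (percent of background)
fold_enrichment(9, 1613, 120, 18000)  # 0.837
```

A thin CLI over the same functions lives at `inst/cli/aquamir.R`
(subcommands `simulate`, `detect`, `refsel`, `normalize`, `de`,
`pipeline`); the `pipeline` subcommand drives `run_profiling()` /
`run_validation()` from a YAML config and writes per-stage CSV/JSON
outputs with an md5 manifest.

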