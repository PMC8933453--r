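# tissueorigin

Biobanks hold large, often decades-old DNA collections extracted either
from whole blood or from lymphoblastoid cell lines (LCLs) — B cells
immortalised in vitro with Epstein–Barr virus — and the record of which
is which is frequently dated, incomplete or wrong.  Because LCL genomes,
methylomes and transcriptomes drift during immortalisation and culture,
knowing the true tissue of origin matters before any (epi)genomic study.
`tissueorigin` implements a real-time-PCR tissue-of-origin test that
settles the question from three genetic features, together with a
three-CpG DNA-methylation age model that shows *why* it matters, and a
synthetic cohort generator so the whole pipeline is testable without
instrument data.

## The test

Three qPCR assays are read against a single-copy *GAPDH* control run on
the same sample:

* **EBV load** — LCLs carry 2–500 episomal EBV genome copies per diploid
  genome; healthy blood carries essentially none.  The score is the
  ratio `100 · Ct_GAPDH / Ct_EBV`: below **91** → blood, above **110** →
  LCL, between → uncertain.  Samples with no EBV amplification are
  imputed at Ct 40.
* **Rearranged TCR-γ** — V(D)J-rearranged T-cell receptor γ is present
  only in blood T cells, never in B-cell-derived LCLs.  The mirrored
  ratio rule applies (`100 · Ct_GAPDH / Ct_TCRγ`, above 80 → blood,
  below 70 → LCL; no amplification imputed at Ct 45).
* **Rearranged TCR-β** — read from the post-PCR melting curve: a
  specific rearranged product melts **above 89.5 °C** (blood), while LCL
  reactions show only primer dimers and non-specific products below it.

Ct values are called threshold-free by the **second-derivative-maximum**
method and melting peaks from the maxima of −dF/dT; per-assay calls are
combined by a **two-of-three vote**, so a single aberrant assay can
never produce a false blood call.  Diagnostic performance follows the
convention *blood = positive; LCL and uncertain = negative*
(sensitivity, specificity, PPV, NPV, accuracy, and concordance against a
database annotation).

The methylation clock is the affine model

```
predicted age = −20.372 + 0.830·ELOVL2(CpG5) + 1.723·KLF14(CpG2) + 0.715·TRIM59(CpG5)
```

evaluated per tissue with the mean absolute deviation (MAD, years) from
chronological age and Pearson R — near-chronological in blood, badly
degraded in LCLs.

## Worked example

```r
library(tissueorigin)

res <- run_origin_pipeline(cohort_config(n_blood = 150, n_lcl = 150, seed = 42))
res
#> <origin_cohort> 300 samples (150 blood, 150 LCL), 90300 raw signal points
#>   combined calls: blood 150, LCL 150, uncertain 0, unclassifiable 0
#>
#> Combined test vs ground truth:
#> Tissue-of-origin test evaluation (blood = positive)
#>   n = 300  (TP 150, FP 0, TN 150, FN 0)
#>   Sensitivity 100.0%  Specificity 100.0%  PPV 100.0%  NPV 100.0%  Accuracy 1.000
#>
#> Methylation age-prediction evaluation
#>   LCL       n = 150  MAD =  23.3 y  R = 0.24
#>   blood     n = 150  MAD =   4.3 y  R = 0.96
```

The simulated cohort is fully labelled, so the combined test is scored
against ground truth: every blood and LCL sample is recovered, with no
false-positive blood calls (PPV 100%) — the property the two-of-three
vote is designed to guarantee.  The clock tracks age in blood to ~4
years but is off by ~23 years and nearly uncorrelated in LCLs, the
signature of a culture-disturbed methylome.  Per-sample scores chain
with the pipe:

```r
library(dplyr)
res$calls |> select(sample_id, ebv_ratio, tcrg_ratio, tcrb_max_tm, combined) |> head(4)
#> # A tibble: 4 × 5
#>   sample_id ebv_ratio tcrg_ratio tcrb_max_tm combined
#>   <chr>         <dbl>      <dbl>       <dbl> <chr>
#> 1 S0001          65.5       90.9        90.9 blood
#> 2 S0002          64.8       90.1        90.4 blood
#> 3 S0003          64.7       85.6        90.8 blood
#> 4 S0004          65.6       92.5        90.9 blood
```

`tidy()` / `glance()` methods give tabular summaries of every result
object, `autoplot()` and `plot_marker_distributions()` the standard
figures, and `inst/cli/tissueorigin.R` exposes the stages
(`simulate`, `call`, `classify`, `evaluate`, `age`, `run-all`) as a
file-in/file-out command line over schema-headed CSV tables.

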