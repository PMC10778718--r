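# edrna

Integrative analysis of **paired plasma-exosomal RNA fold changes** and
**complete-blood-count (CBC) dynamics** for discovering biomarkers of
*early death* (ED) in chemoradiotherapy cohorts.

A minority of patients treated with concurrent chemoradiotherapy (CCRT)
progress within a year and die of disease shortly after, out of proportion
to stage and histology. This package implements a reusable pipeline that
links each patient's pre- versus week-2 exosomal RNA log2 fold change
(log2FC) to the dynamics of their serial blood counts and to outcome, and
distils the result into a small RNA panel and a composite risk score:

1. **CBC dynamics** — for each cell type *c* ∈ {ANC, PLT, Hb, ALC, Mo}:
   baseline *c*0, on-treatment nadir min *c*, geometric mean
   *c*1 = √(*c*0 · min *c*), week-2 value *c*2, recovery ratio
   *c*3 = log(*c*2/*c*0), plus NLR/PLR/LMR ratios; outcome groups
   (ED: progression ≤ 12 mo and disease-specific death ≤ 15 mo;
   progression with survival > 30 mo; no recurrence with follow-up
   > 60 mo) and propensity-score-matched group comparisons.
2. **Expression** — detection filtering (RNAs undetected in ≥ 50% of
   samples removed), TMM normalization, and per-patient
   log2FC = log2(post/pre normalized abundance).
3. **Association** — Pearson correlation of every RNA's log2FC with every
   CBC feature and with the ED/EP indicators, a per-cell-type link-flag
   scheme, and a *homeostasis screen* for RNAs with opposite-signed
   significant correlations to a baseline feature and its recovery ratio.
4. **Network** — RNAs linked to ≥ 3 of 8 hematological factors and to
   both ED and EP, or with |R vs ED| > 0.5, joined by edges where
   pairwise |R| of their log2FC profiles exceeds 0.5 (or 0.6).
5. **Key selection** — exhaustive all-subsets OLS regression of the ED
   indicator on the network RNAs; per-size best models by adjusted R²;
   ncRNAs included in > 50% and mRNAs in > 60% of the retained models;
   plus the RNA(s) linked to **all five** CBC cell types.
6. **Scoring & survival** — composite score
   `lfc(pos) − lfc(neg1) − lfc(neg2)` (ED-positive RNA minus the two
   ED-negative RNAs); Kaplan–Meier disease-specific survival stratified
   at score 0 with a log-rank test and a Wilcoxon comparison by ED status.

A synthetic-cohort generator (`simulate_cohort()`) with planted driver
RNAs and known ground truth makes the whole pipeline testable end to end
without any data download.

## Worked example

```r
library(edrna)

cohort <- simulate_cohort(sim_config(n_patients = 40, seed = 7))
res <- run_pipeline(cohort$clinical, cohort$cbc, cohort$counts)

res$triple
#> $rna_pos
#> [1] "miRNA_001"
#> $rna_neg
#> [1] "lncRNA_001" "mRNA_001"
#> $r_ed
#>  miRNA_001 lncRNA_001   mRNA_001
#>  0.5883456 -0.5428990 -0.5037352

print(res$survival)
#> disease-specific survival at 30 months:
#>  score<0 score>=0
#>    100.0     81.8
#> log-rank p = 0.00402
#> score by ED, Wilcoxon p = 0.00148
#> median follow-up (reverse KM): 74.75872 months

cohort$truth$driver_rna_ids
#> [1] "miRNA_001"  "lncRNA_001" "mRNA_001"
```

The pipeline admitted 10 RNAs into the network, selected the three
planted drivers as the final triple (an ED-positive miRNA and two
ED-negative RNAs, the mRNA being the one linked to all five cell types),
and the composite score split the cohort into a `score<0` group with 100%
30-month disease-specific survival and a `score>=0` group at 81.8%
(log-rank p = 0.004). The Wilcoxon p compares the score between ED and
non-ED patients.

## Package layout

- `R/` — implementation (simulation, CBC dynamics, expression,
  association, network, key selection, scoring/survival, pipeline, I/O).
- `tests/testthat/` — unit, property and acceptance suites; fixtures are
  generated in code.
- `vignettes/edrna-methods.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical conventions, limitations.
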