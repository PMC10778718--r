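---
title: "Methods: linking exosomal RNA fold changes to blood-count dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking exosomal RNA fold changes to blood-count dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Patients receiving concurrent chemoradiotherapy (CCRT) occasionally show
accelerated progression and early disease-specific death (ED) that stage
and histology do not explain. The working model behind this package is
that a failing host response leaves traces in two inexpensive serial
measurements: the dynamics of the complete blood count (CBC) during
treatment, and the change in plasma-exosomal RNA abundance between a
pretreatment draw and a draw in the second on-treatment week. The
pipeline operationalizes that model as a chain of screening steps — each
deliberately simple and transparent — ending in a three-RNA composite
score that stratifies disease-specific survival.

## CBC dynamics features

For each cell type $c \in \{\mathrm{ANC}, \mathrm{PLT}, \mathrm{Hb},
\mathrm{ALC}, \mathrm{Mo}\}$ the per-patient features are

* $c_0$ — pretreatment value,
* $\min c$ — minimum over all on-treatment panels,
* $c_1 = \sqrt{c_0 \cdot \min c}$ — geometric mean of baseline and nadir,
* $c_2$ — the week-2 value,
* $c_3 = \log(c_2 / c_0)$ — the log recovery ratio,

plus the ratios $\mathrm{NLR} = \mathrm{ANC}/\mathrm{ALC}$,
$\mathrm{PLR} = \mathrm{PLT}/\mathrm{ALC}$,
$\mathrm{LMR} = \mathrm{ALC}/\mathrm{Mo}$ formed from the 0- and
1-suffixed values. Units are cells/µL (ANC, ALC, Mo), $10^3$ cells/µL
(PLT) and g/dL (Hb); ratios and $c_3$ are dimensionless. Two conventions
were genuinely open and are fixed as follows:

* **Log base for $c_3$.** Natural log by default, configurable
  (`derive_cbc_dynamics(log_base=)`). Every downstream use of $c_3$ is
  through signs and Pearson correlations, which are invariant to the
  base; only the magnitude of $c_3$ itself changes.
* **Nadir window.** $\min c$ is taken over every on-treatment panel
  (week $\ge 1$), *including* the week-2 draw. Excluding week 2 would
  make $\min c \le c_2$ fail only through the pretreatment draw, which
  is not an on-treatment value; the inclusive window keeps
  $\min c \le c_2$ true by construction.

## Outcome groups

Group 1 (ED) is progression within 12 months plus disease-specific death
within 15; group 2 is progression with survival beyond 30 months; group 3
is no recurrence with follow-up beyond 60 months. Patients fitting none
of the rules stay unassigned and do not enter matched comparisons. The
binary indicators used by the association stage are ED (group 1) and EP
(any progression within 12 months).

## Matching and group tests

Propensity scores come from a logistic regression of arm membership on
the chosen covariates; matching is greedy nearest-neighbour on the logit
scale, without replacement, at ratio 1:1 or 1:2. Determinism is enforced
by processing treated patients in `patient_id` order and breaking
distance ties the same way. No caliper is applied by default (a
`caliper` argument, expressed in SDs of the logit propensity, is
available). Complete separation makes propensities meaningless, so the
fit falls back — with a warning — to exact matching on the joint
covariate strata. Group comparisons use a chi-square test without
continuity correction for categorical variables; continuous variables
get a Shapiro–Wilk check in both arms at $\alpha = 0.05$, then a Welch
t-test if both pass and a Wilcoxon rank-sum test otherwise, with flags at
$p < 0.05$ and $p < 0.1$.

## Expression: filtering, TMM, per-patient log2FC

RNAs undetected in at least half of all samples are removed. Library
scaling uses the trimmed mean of M-values (TMM): the reference sample is
the one whose upper-quartile count (relative to library size) is closest
to the mean; for each sample the log2 abundance ratios against the
reference are doubly trimmed (30% of M-values and 5% of A-values from
each tail) and averaged with inverse asymptotic-variance weights; factors
are rescaled to geometric mean 1. The implementation is validated in the
test suite against edgeR's `calcNormFactors` to $10^{-6}$ on a fixed toy
matrix and to $10^{-10}$ on simulated libraries.

The per-patient fold change for RNA $r$ is

$$\mathrm{log_2FC}_{p,r} = \log_2
  \frac{a_{\mathrm{post}} + \epsilon}{a_{\mathrm{pre}} + \epsilon},
  \qquad a = \frac{\text{count}}{\text{libsize} \times \text{factor}},$$

with pseudocount $\epsilon = 0.5 / \overline{\text{effective libsize}}$
by default (configurable, including $\epsilon = 0$, under which pre/post
swap antisymmetry is exact). A per-patient fold change — rather than a
cohort-level contrast — is the point of the design: it yields one number
per patient per RNA that can be correlated with that patient's CBC
features and outcome. Normalization is joint across all samples by
default; per-pair normalization can be had by subsetting the counts
before calling `tmm_factors()`.

## Association structure

`correlate_all()` computes pairwise-complete Pearson coefficients of
every RNA log2FC column against every CBC feature and the ED/EP
indicators, with two-sided p-values from the $t$ distribution. A
constant column yields `NA`, never 0. "Associated" throughout the
package means $p < 0.05$ **uncorrected**. This is a deliberate screening
convention, not an inferential claim: the admission and selection stages
stack several such screens, and the null behaviour of the whole chain is
what the calibration suite checks (the fraction of null RNAs flagged
against any single CBC variable sits in the binomial 99% band around
0.05).

Link flags come in two variants, reflecting the two places they are
used: admission to the network tests the baseline-side features
($c_0$, $\min c$, $c_1$); node annotation and the all-CBC criterion test
all five features ($c_0, c_1, c_2, c_3, \min c$). Ratio flags use the
0/1-suffixed variants in both.

The **homeostasis screen** flags RNA $r$ for cell type $c$ when (i) the
cohort-level correlation between a baseline feature $b \in \{c_0, c_1\}$
and $c_3$ is negative, (ii) $r$ is significantly correlated with both
$b$ and $c_3$, and (iii) with opposite signs — i.e. the RNA tracks the
push–pull between starting level and recovery. An alternative reading
("the RNA *causes* the negative $b$–$c_3$ correlation" as a
leave-one-out change in that correlation) was considered and not
implemented; the opposite-sign rule is the minimal operationalization
and is what the flag semantics document. Flagged pairs are classified by
ED-correlation sign (red/blue) and cell family (ANC/PLT solid,
Hb/ALC/Mo dashed). ED correlations use the binary ED indicator, not
survival time.

## The ED network

An RNA is admitted if it is linked to at least three of the eight
hematological factors *and* significantly correlated with both ED and
EP, or if $|R_{\mathrm{ED}}| > 0.5$. Edges connect admitted RNAs with
pairwise $|R| > 0.5$ (or $0.6$) between their log2FC profiles. The
absolute value matters: strongly anti-correlated partners are
biologically the interesting case and must connect; the signed
coefficient is kept as an edge attribute. Isolated admitted RNAs are
dropped, so reported node counts describe the connected graph —
which is why the same admitted pool yields different node counts at the
two thresholds. Edge existence requires only the magnitude threshold,
not a separate significance test (at $n = 40$, $|R| > 0.5$ corresponds
to $p < 0.002$ anyway).

## Key-RNA selection

All predictor subsets of the network RNAs up to
$k_{\max} = \min(10, \lfloor n/4 \rfloor, p)$ are fit by OLS against the
binary ED indicator (a linear probability model — the natural choice
given that best-subset machinery is least-squares, and ED is the outcome
the selected panel is validated against). The retained-model pool is the
per-size champions by adjusted $R^2$; ties break lexicographically on
member names and predictors are ordered alphabetically internally, so
results are independent of column order. Exactly collinear predictors
are dropped up front with a warning. Inclusion frequency is the fraction
of retained models containing an RNA; ncRNAs above 0.5 and mRNAs above
0.6 (strictly) are "key", unioned over the two network thresholds.
Finally, the all-CBC criterion returns network RNAs whose annotation
flags cover all five cell types.

A caution the test suite makes explicit: under pure noise the per-size
champions tend to share whichever predictor happens to be the
chance-best in that dataset, so *some* predictor usually shows a high
inclusion frequency. What is controlled is that no *fixed* predictor
recurs across datasets (per-RNA exceedance $\approx 1/p$), and that under
a null cohort essentially nothing is admitted to the network in the
first place — selection control lives in admission, not in the
frequency statistic alone.

## Composite score and survival

With an ED-positive RNA $r^{+}$ and ED-negative RNAs $r^{-}_1, r^{-}_2$,
the score is
$s_p = \mathrm{lfc}(r^{+}) - \mathrm{lfc}(r^{-}_1) - \mathrm{lfc}(r^{-}_2)$,
and patients split at the absolute threshold $s < 0$ versus $s \ge 0$.
This sign assignment is the only one under which "score below zero"
coherently marks the favourable profile given the components' ED signs.
Disease-specific survival treats disease deaths as events and censors
other deaths at their death time; the group survival is read off the
Kaplan–Meier step function at 30 months (left-continuous convention);
the log-rank test uses the full follow-up, with the 30-month rates
reported descriptively; median follow-up is the reverse-KM median. In
the full pipeline the triple is drawn from the key-RNA union (ncRNA
slots) and the all-CBC set (mRNA slot), with documented fallbacks to the
most strongly ED-correlated admitted candidates of the required sign, so
degraded cohorts still yield a deterministic, inspectable choice.

The optional over-representation step is a one-sided Fisher exact test
per gene set with Benjamini–Hochberg correction — a fully local
replacement for web-based enrichment services, which are out of scope.

# The synthetic-cohort generator

`simulate_cohort()` emulates the study design the pipeline targets: a
cohort with paired (pre / week-2) exosomal RNA counts, weekly CBC panels
during CCRT, and long-term outcomes. One latent score $z_i$ per patient
drives everything:

* **Outcome groups.** The top `ed_fraction` of patients by $z$ form the
  ED group (default 0.1 — matching a cohort whose 30-month
  disease-specific survival is about 90%), the next 30% progress late
  but survive beyond 30 months, the rest are followed past 60 months
  without recurrence. Rank-based assignment keeps group sizes
  deterministic. Survival times are uniform within each group's window;
  only group membership and the 30-month horizon matter downstream.
* **CBC trajectories.** Baselines are lognormal at clinically typical
  locations (ANC 4000/µL, PLT 250·10³/µL, Hb 12.5 g/dL, ALC 1800/µL,
  Mo 450/µL). On-treatment draws decline toward a per-cell nadir
  fraction (lymphocytes suppressed most), carry log-scale noise, regress
  toward the cohort mean (coefficient 0.5 on the centred log baseline —
  this reproduces the negative baseline-versus-recovery correlation the
  homeostasis screen is predicated on), and share a factor
  $u_i = \rho z_i + \sqrt{1-\rho^2}\,\varepsilon_i$ with
  $\rho = $ `cbc_coupling`, signed per cell type (neutrophilia,
  thrombocytosis, anaemia, lymphopenia, monocytosis in poor-prognosis
  patients).
* **Counts.** Negative-binomial (dispersion 0.2) around lognormal
  per-RNA means (median `baseline_mean_counts = 100`; exosome libraries
  are shallow) and lognormal per-sample size factors (sd 0.3 on the log
  scale), which makes TMM normalization do real work. Planted drivers
  shift their post-treatment mean by
  $2^{\pm\,\mathrm{driver\_effect} \times z_i}$, cycling through the
  roles ED-positive miRNA, ED-negative lncRNA, ED-negative mRNA; all
  other RNAs are null.

Identical seeds give bit-identical cohorts. The default catalogue (200
RNAs across eight biotypes) is a desk-scale choice; the null-calibration
suite uses 2000 RNAs, and the planted-recovery suite runs 20 cohorts of
40 patients — sizes chosen so the full test suite and the acceptance
script complete in well under a minute each while leaving the binomial
bands tight enough to be informative.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: biotype-specific abundance and noise
profiles, correlated co-expression among non-driver RNAs, missing CBC
panels, measurement error in the clinical table, informative censoring,
competing risks, batch effects between sequencing providers, and any
nonlinearity in the RNA–CBC coupling. Recovery rates on synthetic
cohorts are an internal-consistency check of the pipeline, not an
estimate of clinical performance.

# Numerical conventions and degenerate inputs

* TMM trims are the established 30%/5% defaults; an all-zero library is
  an error naming the sample; a sample identical to the reference gets
  factor exactly 1.
* Correlations with fewer than 3 complete pairs, or against a constant
  column, are `NA` and never silently 0; $|R| = 1$ maps to $p = 0$.
* The exhaustive search requires $n > k_{\max} + 1$ and a non-constant
  outcome; singular subsets (beyond the up-front collinearity drop) are
  skipped.
* An empty network is a warning plus an empty graph; the pipeline then
  returns empty key sets and `NULL` score/survival slots rather than
  failing.
* A single score group skips the log-rank test with a message; KM is
  still computed.

# Known limitations

* The screening threshold ($p < 0.05$, uncorrected) is inherited from
  the design the package implements; it is calibrated, but it is not an
  error-controlled discovery procedure.
* The linear-probability OLS for subset search is a pragmatic stand-in
  for a logistic model; with a rare binary outcome, adjusted $R^2$
  rankings can be unstable at small $n$.
* Greedy nearest-neighbour matching is order-dependent by construction;
  determinism is guaranteed, optimality is not.
* The composite score's absolute-zero threshold presumes log2FC values
  centred by the normalization; a systematic shift in normalization
  would move patients across groups.
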