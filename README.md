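# gapstrat

Prognostic stratification of primary glioblastoma (GBM) by **gene
amplification profile (GAP)**, for researchers working with SNP-array
copy-number data and survival follow-up.

Most molecular GBM classifications are hard to run in routine diagnostics.
The GAP scheme is deliberately simple: call *high-level* amplicons — more
than 7 DNA copies, i.e. values above **θ = 4.8** arbitrary copy-number
units (diploid = 2), a threshold that excludes broad 3–4-copy polyploid
gains — from paired tumor/normal probe tracks, reduce them to amplified
chromosome **arms** ("chromosomal regions"), and assign each tumor

* one of five classes: `NO_AMP`, `EGFR_ONLY` (isolated 7p11.2/EGFR),
  `NON_EGFR_SINGLE`, `MULTI_WITH_EGFR`, `MULTI_WITHOUT_EGFR`, and
* one of two risk groups:
  `FAVORABLE = NO_AMP ∪ EGFR_ONLY ∪ MULTI_WITH_EGFR` vs
  `UNFAVORABLE = NON_EGFR_SINGLE ∪ MULTI_WITHOUT_EGFR`.

Prognostic impact is quantified with from-scratch survival machinery:
Kaplan–Meier product-limit curves with the *smallest t such that
S(t) ≤ 0.5* median convention, k-group log-rank tests (hypergeometric
variance), and Cox proportional-hazards regression (Breslow ties,
Newton–Raphson) with forward stepwise selection gated by univariate
significance.

The package bundles (a) a synthetic paired-cohort simulator whose stated
world matches the analysis assumptions (focal amplicons at 7p11.2/4q12/
12q13–15/1q32.1, polyploid gains, shared germline CNVs, Gaussian probe
noise, exponential class-specific survival), and (b) an 80-patient
reference cohort transcribed from the source study's printed tables, so
everything runs offline.

## Worked example

```r
library(gapstrat)
rep <- reproduce_paper()

unlist(rep$class_counts)
#>  NO_AMP  EGFR_ONLY  NON_EGFR_SINGLE  MULTI_WITH_EGFR  MULTI_WITHOUT_EGFR
#>      35         17               10               13                   5

rep$included_n              # survival inclusion filter (of 80 patients)
#> 76

unlist(rep$km_median_by_class)   # months
#>  NO_AMP  EGFR_ONLY  NON_EGFR_SINGLE  MULTI_WITH_EGFR  MULTI_WITHOUT_EGFR
#>      13         17                6               13                   8

unlist(rep$km_median_by_risk)    # months
#>  FAVORABLE  UNFAVORABLE
#>         14            6

rep$logrank_2group      # chisq 26.5, df 1, p 2.7e-07
rep$stepwise$selected   # "chemo_category" "risk"
round(unlist(rep$stepwise$hr), 2)
#> chemo_category=Other  chemo_category=None  risk=UNFAVORABLE
#>                 1.52                10.55              4.36
```

Reading: 45/80 tumors carry amplification and EGFR is involved in 30;
after excluding first-month deaths and under-followed survivors, 76
patients remain. Tumors with non-EGFR amplification (single region median
6 months, multiple regions 8) fare far worse than the favorable pool
(median 14 months); the two-group split and chemotherapy are the
covariates retained by forward stepwise Cox selection (unfavorable-GAP
hazard ratio 4.4, 95% CI 2.1–9.1).

The synthetic route exercises the same pipeline end to end:

```r
ann <- default_annotation()
cfg <- sim_config(seed = 7)                       # sigma = 0.4, 50 kb grid
p   <- simulate_pair(cfg, "MULTI_WITH_EGFR", 42, ann)
res <- call_sample(p$tumor, p$normal, caller_config(), ann)
classify_gap(build_profile(res$amplicons, p$id))
#> "MULTI_WITH_EGFR"
```

A file-driven CLI wraps the stages
(`simulate | call | classify | survive | reproduce-paper`):

```sh
Rscript inst/scripts/gapstrat-cli.R simulate --out sim/ --n 20 --seed 1
Rscript inst/scripts/gapstrat-cli.R call --tumor sim/tumor_probes.tsv \
        --normal sim/normal_probes.tsv --out calls/
Rscript inst/scripts/gapstrat-cli.R classify --amplicons calls/amplicons.tsv \
        --out classes.tsv
Rscript inst/scripts/gapstrat-cli.R reproduce-paper --out report.json
```

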