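# pvdiss

Pharmacovigilance signal detection for drug-induced Sweet's syndrome
(DISS, acute febrile neutrophilic dermatosis) from spontaneous
adverse-event reports.

Sweet's syndrome is a rare neutrophilic dermatosis that can be triggered by
a broad and shifting spectrum of drugs. Because no trial will ever be
powered for an event this rare, the evidence comes from spontaneous-report
databases such as FAERS: millions of multi-table reports, riddled with
duplicates, free-text drug names, partial dates and missing demographics.
`pvdiss` implements the complete analysis chain a pharmacoepidemiologist
needs to turn those reports into a vetted list of suspect drugs, and ships
a synthetic report generator with planted associations so every stage can
be validated against known truth.

## What it computes

**Disproportionality.** For each drug, the report universe is collapsed to
the 2×2 table (a = reports with drug and event, b = drug only, c = event
only, d = neither) and the reporting odds ratio is

    ROR = (a/c) / (b/d),   95% CI = exp( ln ROR ± 1.96 √(1/a + 1/b + 1/c + 1/d) )

with a Fisher exact p-value and Benjamini–Hochberg FDR adjustment across
all tested drugs. A *signal* is a drug with at least 3 case reports and a
CI lower bound above 1. Exposure is primary-suspect (role `PS`) only.

**Deduplication.** Among reports sharing a CASEID, the one with the most
recent FDA receipt date (FDA_DT) is retained; ties go to the highest
PRIMARYID. Partial dates are ordered by the earliest date they could
denote.

**Confounding by indication.** Three predefined analytical datasets: the
main analysis drops reports with malignancy- and/or immune-related
indications; sensitivity A drops malignancy only; sensitivity B drops
immune only. Within each, signal drugs plus age and sex enter an
L1-penalized (LASSO) logistic model tuned by stratified 10-fold
cross-validation (λ_min / λ_1se); the selected variables are refit by
ordinary logistic regression, reported as odds ratios with FDR-adjusted
p-values and in-sample AUC (DeLong CI).

**Time-to-onset.** Days from therapy start to event onset, summarized as
median/IQR and interval bins, and fitted by a maximum-likelihood Weibull
model (shape k, scale λ in days).

**Context.** Drug co-occurrence networks over case reports, ATC-class
distributions with chi-square sex/age stratification, annual linear
trends, and a cross-database evidence matrix combining a replication
screen on a second corpus with curated literature/label annotations.

## Worked example

The bundled demo configuration simulates 20,000 reports from a 40-drug
catalogue with four planted associations (odds-ratio multipliers 6–12),
5% duplicate injection, realistic missingness and Weibull onset latencies:

```r
library(pvdiss)
run <- run_pipeline(demo_config(seed = 1, n_reports = 20000))
run
#> Pharmacovigilance pipeline run
#>   raw reports 21000 -> deduplicated 20000 (dropped 1000)
#>   cases: 338; positive signals: 4
#>   onset: median 30 d (IQR 9-94); Weibull k=0.80, lambda=50 d
#> main: 3 candidates -> 5 selected -> 3 significant; AUC 0.690
#> sensitivity_A: 4 candidates -> 5 selected -> 4 significant; AUC 0.702
#> sensitivity_B: 3 candidates -> 3 selected -> 3 significant; AUC 0.671
#> cross-scheme significant overlap: 3 drug(s)

head(run$screen[order(-run$screen$signal, run$screen$p_adj),
     c("drug", "n", "ror", "ci_low", "ci_high", "p_adj", "signal")], 6)
#>                           drug  n   ror ci_low ci_high    p_adj signal
#>  sulfamethoxazole/trimethoprim 48 6.643 4.8304   9.135 3.87e-20   TRUE
#>                    azacitidine 44 6.346 4.5614   8.829 3.62e-18   TRUE
#>                       drug_003 33 4.651 3.2087   6.742 1.22e-10   TRUE
#>                     adalimumab 31 4.215 2.8804   6.168 3.37e-09   TRUE
#>                       drug_009  1 0.112 0.0157   0.800 1.53e-02  FALSE
#>                       drug_013  1 0.112 0.0157   0.801 1.53e-02  FALSE
```

Reading the screen: the four planted drugs are flagged — each has dozens
of case reports and an ROR whose CI excludes 1 — while every null drug is
rejected by the case-count or CI criterion. The 1,000 injected duplicate
rows are removed by the FDA retention rule before any counting, and the
onset summary reflects the generator's configured acute-onset Weibull law.
`run$models` holds the per-scheme LASSO and logistic fits,
`run$network` the co-occurrence graph, and `run$evidence` the evidence
matrix.

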