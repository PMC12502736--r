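---
title: "Methods: disproportionality analysis of drug-induced Sweet's syndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality analysis of drug-induced Sweet's syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pvdiss` analyzes spontaneous adverse-event reports for drug-induced
Sweet's syndrome (DISS), identified by the MedDRA preferred term
"Sweet syndrome" (code 10042458). This vignette documents the statistical
procedures, the parameters that matter, the synthetic-data model used to
validate them, and the design decisions taken where the methodology was
genuinely open.

## Report model and deduplication

A report is a row in the demographics table (keyed by PRIMARYID) plus
child rows for drugs (with role codes PS/SS/C/I), reactions, outcomes,
reporter sources, therapy dates and indications. Spontaneous databases
contain versioned resubmissions of the same case, so counting reports
directly would double-count: among rows sharing a CASEID we retain the one
with the most recent FDA receipt date, breaking ties by the highest
PRIMARYID. Partial receipt dates (YYYY or YYYYMM) are compared after
padding to the earliest date they could denote — a deterministic ordering
that invents no precision; the affected drops are recorded in the
deduplication ledger. Reports lacking a CASEID cannot be versioned and are
kept as singletons, with a logged count. The operation is idempotent and
order-independent (property-tested on randomized corpora with partial
dates).

## Case definition and exposure

A case is a deduplicated report whose reactions contain the target PT
(exact, case-insensitive). Exposure is restricted to primary-suspect (PS)
drugs: concomitant medication is deliberately excluded from the estimand,
because co-medication with corticosteroids or immunosuppressants is
ubiquitous in this population and would swamp the signal list. Cases
whose only drugs are concomitant are retained with zero exposures, not
dropped. Free-text drug names are trimmed, whitespace-collapsed and
case-folded, then passed through a user-supplied synonym table (the
configurable stand-in for a licensed drug dictionary; unmapped names pass
through flagged). Reports with several PS drugs contribute exposure to
each of them.

## Disproportionality

For each drug the report universe collapses to the 2×2 table
(a, b, c, d) and the reporting odds ratio ROR = (a/c)/(b/d) = ad/bc, with
the Wald interval exp(ln ROR ± z·√(1/a+1/b+1/c+1/d)), z = 1.96 at
α = 0.05. The per-drug p-value is the two-sided Fisher exact test
(point-probability convention: all fixed-margin tables with point
probability not exceeding the observed one; this matches
`stats::fisher.test` and the enumeration oracle used in the tests), and
the family of all tested drugs is adjusted by Benjamini–Hochberg.

The signal rule is: at least `min_cases` reports (default 3) **and** CI
lower bound above 1. The FDR-adjusted p is reported alongside but does not
enter the flag — the rule is the conventional count-plus-CI criterion.
Two numerical choices deserve note:

* **Zero cells.** The ROR formula presumes non-zero cells. By default a
  zero-cell table yields an undefined (NA) estimate with a flag; the
  Haldane–Anscombe +0.5 correction is available via `haldane = TRUE` but
  is off by default, since applying it silently changes the estimand.
* **Case-count threshold.** Published criteria oscillate between
  "more than 3" and "at least 3" reports. The default is ≥3; the strict
  reading is one argument away (`min_cases = 4`).
* **FDR family.** The adjustment family is all drugs tested in the given
  screen (every drug with ≥1 case report, unless an explicit drug list is
  supplied); reporter-filtered reruns (e.g. restricted to medical-doctor
  reports) adjust within their own universe.

## Indication-exclusion schemes

Sweet's syndrome co-occurs with malignancy and immune-mediated disease,
so indications confound naïvely screened drug lists. Three predefined
datasets address this: *main* excludes reports with malignancy- and/or
immune-related indications, *sensitivity A* excludes malignancy only,
*sensitivity B* excludes immune only (a *full* scheme applies no
exclusion). The shipped term lists (leukaemia/lymphoma/myeloma/carcinoma/…
and Crohn's/colitis/rheumatoid/lupus/psoriasis/…) are deliberately
editable seed lists matched by case-insensitive substring; users should
review them before a production run. Reports without indication rows are
retained in every scheme — exclusion criteria cannot be evaluated on
missing data — and the retention algebra (main = A ∩ B) is asserted in
the tests.

## Risk-factor modelling

Within each scheme, the flagged drugs plus age and sex are candidate
predictors of case status over all retained reports (no control sampling:
nothing in the design requires it, and subsampling would discard
information). Rows missing age or sex are dropped for modelling
(complete-case; the count is reported) since the package does not impute.
The LASSO path has 100 log-spaced λ values spanning four decades below
λ_max; folds (10 by default) are stratified by case status because the
outcome is rare. λ_min optimizes the mean cross-validated criterion and
λ_1se is the most parsimonious model within one standard error of it. The
CV criterion is AUC by default, with binomial deviance available — the
two are both in common use and can disagree; selection is reported for
both λ choices. Selected variables are refit by ordinary logistic
regression; Wald CIs on the log-odds scale are exponentiated, p-values
are FDR-adjusted within the model, and the significant set is
adjusted p < 0.05 with OR CI lower bound ≥ 1. Discrimination is the
in-sample AUC of the refitted model (tie-corrected Mann–Whitney), with a
DeLong CI, falling back to a seeded 2,000-resample bootstrap when the
DeLong variance is degenerate. Perfect separation is flagged (including
the saturated-fit case that raises no `glm` warning, detected by fitted
probabilities within 1e-10 of 0 or 1) rather than silently reported.

## Time-to-onset

Latency is the day count from the earliest complete therapy-start date of
a suspect drug that does not fall after the complete event-onset date;
reports with partial or missing dates are incomplete, and reports whose
starts all postdate the event are excluded as negative intervals (both
counted). When a suspect drug has several therapy episodes, the earliest
qualifying start is used — the conservative, longest-latency attribution.
Latencies are summarized by median/IQR (linear-interpolation quartiles,
`type = 7`; the convention is stated because published tables rarely say)
and by interval bins (0–30, 31–60, 61–90, 91–180, 181–365, >365 days;
edges configurable). The Weibull model is fit by maximum likelihood on
continuous days; same-day onsets are shifted to 0.5 days so the
acute-onset mass is kept. Intervals beyond 1,000 days are retained by
default. Fit sanity is property-tested: rescaling time by 7 rescales the
scale estimate and leaves the shape invariant, and simulated
Weibull(1.2, 60 d) data are recovered within 10% at n = 5,000.

## Synthetic corpus generator

The generator exists so the pipeline's operating characteristics can be
measured against known truth. Each simulated report draws one PS drug
uniformly from a catalogue plus 0–4 concomitants; the target PT occurs
with background probability 0.01, tilted on the odds scale for planted
drugs so that a drug's expected ROR equals its configured multiplier —
truth is specified on the same scale as the estimand. Onset latencies for
target-PT reports follow Weibull(shape 0.9, scale 60 d), a right-skewed,
acute-onset-heavy law plausible for this event. Duplicates are injected
by cloning reports under a new PRIMARYID with a later receipt date
(exactly the configuration the retention rule must resolve). Default
missingness follows the demographic profile typical of this cohort: age
22.6%, weight 84.5%, sex 10.3%, indications 6.3% absent, with the
reporter-occupation and country mixes set to the published cohort's
proportions. A configurable fraction (default 5%) of therapy/onset dates
is degraded to month or year precision to exercise partial-date handling.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: drug-name misspellings beyond case/whitespace
noise, therapy-episode multiplicity, correlated exposure (real
polypharmacy is structured, not uniform), reporting-culture differences
across countries, event-dependent reporting delays, and the MedDRA
hierarchy (the vocabulary is a flat PT list). Real FAERS runs therefore
still require curated synonym/ATC tables and scheme term lists.

## Problem sizes

The validation suite measures the screen's operating characteristics on
corpora of 100,000 reports (5 drugs planted at multiplier 10, 50 null
drugs, 5 seeds: all planted drugs must be flagged, at most 5% of nulls),
the LASSO→logistic chain on 40,000-report corpora (5 planted, 35 null,
5 seeds), Weibull recovery at n = 5,000 (5 seeds), and estimator oracles
(exact recounts, Fisher enumeration, BH step-up, chi-square Σ(O−E)²/E,
rank-formula AUC) on hundreds of small randomized fixtures. The demo
pipeline uses 20,000 reports. These sizes resolve the planted effects
comfortably while keeping a full run of suite plus acceptance script in
the minutes range.

## Known limitations

Disproportionality measures reporting association, not causation or
incidence; the ROR inherits every reporting bias in the database. The
evidence matrix ingests literature and label support as a curated
annotation table — the package performs no retrieval. ISR-era (pre-2012)
FAERS schemas are accepted only through a user-supplied column alias map.
The external-corpus replication assumes the second database can be
mapped to the minimal report/drug/role/PT schema; database-native
statistics (e.g. Bayesian information components) are out of scope.
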