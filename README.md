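# recoverydebt

Ecosystems recovering from anthropogenic disturbance — abandoned farmland,
logged forest, eutrophied lakes, overfished reefs — typically run a deficit
of abundance, diversity and biogeochemical function relative to undisturbed
reference systems for years to decades, even when they eventually recover in
full. `recoverydebt` quantifies that interim deficit, the **per-annum
recovery debt**, and pools it across studies with a three-level
random-effects meta-analysis. It is aimed at restoration ecologists and
meta-analysts working with databases of reference-vs-recovery comparisons.

## The statistic

Each record is a comparison (X_s, X_e, X_r, T): the outcome value at the
start and end of the observed recovery window, the reference value, and the
elapsed time in years. Recovery is interpolated exponentially,
x(t) = X_s·e^{rt} with r = log(X_e/X_s)/T (a linear variant is available),
and the debt is the area between the reference line and the trajectory:

    RD   = X_r·T − AUC,        AUC = (X_e − X_s)·T / log(X_e/X_s)
    RD_t = RD / T              (per-annum debt)
    debt ratio = 100·RD_t / |X_r|   (% of reference, the pooled effect size)

Values above the reference (overshoot) are reflected with Z = X_r²/v, which
bounds every ratio by 100%; zero endpoints or references receive a small
additive constant selected among nine candidate strategies by Mann–Whitney
distribution matching against the zero-free records. Debt ratios are pooled
with a three-level model (effects nested in studies, REML variance
components via `metafor::rma.mv`), with within-metric imputation of the
typically ~79% missing sampling variances, Higgins' I² on the
variance-reporting subset, omnibus Q_M moderator tests and per-category
estimates.

A synthetic-database generator constructs records whose forward debt
computation returns a drawn ground-truth ratio exactly, so every estimator
is testable end to end.

## Worked example

One record recovering from 2 to 8 against a reference of 10 over 10 years:

```r
library(recoverydebt)
df <- tibble::tibble(x_start = 2, x_end = 8, x_ref = 10, t_years = 10)
compute_debt(df)[, c("scenario", "method", "r", "auc", "rd_per_annum", "ratio_pct")]
#>   scenario      method        r     auc rd_per_annum ratio_pct
#> 1        a exponential 0.138629 43.2809      5.67191   56.7191
```

The rate r = log(4)/10; the trajectory averages 4.33 units so the system ran
an annual deficit of 5.67 units, i.e. **56.7% of the reference level per
year** over the decade. A full analysis of a (here synthetic) database:

```r
db <- generate_recovery_db(synthetic_config(seed = 1))
report <- run_full_analysis(db)
report
#> Recovery-debt analysis (exponential interpolation)
#>   587 usable records in 5 scenarios; 1 stage error(s)
#>   Pooled per-annum debt ratios (%):
#>     abundance    48 [48, 49]  k=314, studies=138
#>     diversity    29 [28, 30]  k=159, studies=106
#>     carbon       37 [35, 38]  k=70, studies=55
#>     nitrogen     36 [34, 38]  k=44, studies=40
```

Each line is a pooled mean debt ratio with its 95% CI, the number of effects
k and of studies (the generator's true means are 48.5, 30, 37 and 36, all
covered). The "stage error" is a disturbance category with too few carbon
effects to enter a moderator fit — reported, never silently dropped
(`report$errors`). `report$categories`, `report$qm`, `report$i2` and
`report$times` hold the per-category tables, moderator tests, heterogeneity
indices and recovery-time summaries; `write_report(report, dir)` writes one
CSV per table plus a plain-text summary, and `autoplot(report)` draws the
category panels. Real databases enter through
`read_outcome_measures(path, mapping)`, where `mapping` adapts foreign
column headers to the canonical schema.

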