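# faersignal

Post-marketing pharmacovigilance asks a deceptively simple question: among
the millions of spontaneous adverse-event reports that regulators collect,
is a given drug reported with a given event *more often than you would
expect by chance*? `faersignal` is a tidyverse-native R toolkit that answers
it end to end for FAERS-style data (the FDA Adverse Event Reporting System's
quarterly `$`-delimited ASCII tables): report cleaning and deduplication,
case extraction for a target drug, MedDRA preferred-term (PT) to
system-organ-class (SOC) rollup, four-algorithm disproportionality
screening, Table-1-style cohort description, and Weibull time-to-onset
analysis. It is aimed at drug-safety researchers and biostatisticians who
want an auditable, scriptable alternative to ad-hoc SQL pipelines.

Because real FAERS extracts are large and MedDRA is licensed, the package
ships a self-auditing synthetic-report generator with known ground truth
(true reporting-rate ratios, true onset distributions, injected duplicate
versions, deleted cases, partial and reversed dates), so the entire pipeline
is exercised and tested without any download.

## The statistics

Every drug–event pair is reduced to a 2×2 contingency table — `a` reports
with the drug and the event, `b` with the drug and other events, `c` with
other drugs and the event, `d` the remainder, `N = a+b+c+d` — and screened
with four standard algorithms:

- **ROR** (reporting odds ratio): `ROR = ad/bc`, 95% CI
  `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`; criterion `lo95 > 1, a ≥ 3`.
- **PRR** (proportional reporting ratio): `PRR = [a/(a+b)] / [c/(c+d)]`
  with the 2×2 chi-squared `χ² = N(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)]`;
  criterion `PRR ≥ 2, χ² ≥ 4, a ≥ 3`.
- **IC** (Bayesian information component): with `E = (a+b)(a+c)/N`,
  `IC = log₂[(a+0.5)/(E+0.5)]` and the credibility lower bound
  `IC025 = IC − 3.3(a+0.5)^(−1/2) − 2(a+0.5)^(−3/2)`; criterion `IC025 > 0`.
- **EBGM** (empirical Bayes geometric mean): closed-form
  `EBGM = aN/[(a+b)(a+c)]` with `EBGM05 = exp(ln EBGM − 1.645·√(1/a+1/b+1/c+1/d))`,
  or the full two-component gamma-Poisson shrinker (`mgps_fit()` +
  `ebgm_full()`); criterion `EBGM05 > 2`.

A pair is a **signal** only when all four criteria hold simultaneously —
the conjunction is deliberately conservative and replaces any
multiple-testing correction.

Time-to-onset (event date minus therapy start, whole days, day-precision
dates only) is summarised by medians and quartiles and fitted with a
two-parameter Weibull; a shape `β` whose 95% CI lies entirely below 1 marks
an *early failure* profile (hazard decreasing over time), above 1
*wear-out*, and spanning 1 *random*.

## Worked example

```r
library(faersignal)

sim <- simulate_reports(sim_config(n_cases = 5000, seed = 42))
dir <- tempfile()
write_faers(sim, dir)
res <- run_pipeline(dir, c("rucaparib", "rubraca"), file.path(dir, "out"))

glance(res$screen_pt)
#> # A tibble: 1 × 3
#>   n_terms n_signals n_socs_signal
#>     <int>     <int>         <int>
#> 1      20         2             2
```

Twenty PTs had at least three target-drug reports; exactly the two terms
the generator planted with strong reporting-rate ratios come out as joint
signals:

```r
dplyr::select(tibble::as_tibble(res$screen_pt),
              term, a, ror, ror_lo95, prr, ic025, ebgm05, signal)
#> # A tibble: 20 × 8
#>   term               a   ror ror_lo95   prr  ic025 ebgm05 signal
#>   <chr>          <dbl> <dbl>    <dbl> <dbl>  <dbl>  <dbl> <lgl>
#> 1 Anaemia           25 4.33     2.65  4.19   0.904  2.05  TRUE
#> 2 Neutropenia        4 2.31     0.757 2.30  -0.911  0.789 FALSE
#> 3 Nausea           158 8.34     6.62  6.39   1.72   3.30  TRUE
#> 4 Diarrhoea         18 1.40     0.845 1.39  -0.389  0.871 FALSE
#> ...
```

`Nausea` was planted at a true ratio of 8 and `Anaemia` at 5: both clear
all four criteria. `Neutropenia` (true ratio 1) shows an elevated point
ROR purely by chance, and the joint rule correctly leaves it unflagged.
Onset times pooled over all reported SOCs fit an early-failure Weibull:

```r
fit_weibull(res$tto$values[[which(res$tto$group == "all")]])
#> Weibull fit (n = 389, 144 zero-day onsets mapped to >0)
#>   scale alpha: 18.02 (13.50-24.05) days
#>   shape beta : 0.37 (0.34-0.39)  ->  early failure type
```

The shape estimate 0.37 (CI below 1) says the reporting hazard is highest
right after the start of therapy and declines thereafter — consistent with
the generator's true onset distribution (scale 16.57 days, shape 0.28).

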