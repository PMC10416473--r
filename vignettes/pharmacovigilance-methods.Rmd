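---
title: "Methods: disproportionality screening and time-to-onset analysis of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening and time-to-onset analysis of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem and the data model

Spontaneous-report databases such as FAERS have no denominators: we observe
only which drug–event pairs were *reported*, never how many patients took a
drug. Incidence is therefore uncomputable, and the entire analysis rests on
*disproportionality*: comparing how often a pair is reported against what
independence of drug and event would predict inside the database itself.
This assumption — that reporting behaviour is exchangeable enough across
drugs for the database to act as its own control — is the foundational
caveat of every statistic below.

A raw extract consists of quarterly `$`-delimited tables (DEMO, DRUG, REAC,
THER, OUTC, INDI) keyed by a report version (`PRIMARYID`) nested in a case
(`CASEID`). Before any statistic is computed the package:

1. **deduplicates**: keeps, per case, the numerically highest `PRIMARYID`
   (the latest version) and drops cases on the deleted-case list. Ties on
   an identical `PRIMARYID` keep the first row in file order — the rule
   must be deterministic, and nothing in the data distinguishes such rows;
2. **extracts target cases**: a case counts as exposed when any DRUG row
   matches a drug-name synonym in `drugname` *or* `prod_ai`
   (case-insensitive substring after trimming — trade names, salts and
   free-text spellings make exact matching lossy; an exact mode exists for
   sensitivity analysis) with role code `PS` (primary suspect);
3. **normalises events** to one mention per (case, PT) pair, so duplicate
   reaction rows from report versioning cannot inflate counts, and rolls
   PTs up to SOCs through a user-supplied dictionary (MedDRA itself is
   licensed and never shipped). A PT can link to several SOCs; the
   `primary` policy keeps one row per PT, the `all` policy one per link.
   The counting unit everywhere is the unique (case, term) pair — the
   alternative (raw event rows) is supported upstream but not used by
   default, since published screens count cases.

## The four algorithms and the joint rule

For each term at a given level the 2×2 table (`a`, `b`, `c`, `d`;
`N = a+b+c+d`; expected count `E = (a+b)(a+c)/N`) feeds four estimators,
two frequentist and two shrinkage-based:

| statistic | definition | criterion |
|---|---|---|
| ROR | $ad/bc$, CI $\exp(\ln ROR \pm 1.96\,s)$, $s=\sqrt{1/a+1/b+1/c+1/d}$ | lower 95% bound > 1, $a \ge$ `min_count` |
| PRR | $\frac{a/(a+b)}{c/(c+d)}$, $\chi^2 = \frac{N(ad-bc)^2}{(a+b)(c+d)(a+c)(b+d)}$ | PRR ≥ 2 and $\chi^2 \ge 4$ and $a \ge$ `min_count` |
| IC | $\log_2\frac{a+0.5}{E+0.5}$, $IC_{025} = IC - 3.3(a+0.5)^{-1/2} - 2(a+0.5)^{-3/2}$ | $IC_{025} > 0$ |
| EBGM | $aN/[(a+b)(a+c)]$, $EBGM_{05} = \exp(\ln EBGM - 1.645\,s)$ | $EBGM_{05} > 2$ |

A term is a **signal** only when all four criteria hold at once. The
conjunction is the guard against chance findings: no multiple-testing
correction is applied, deliberately, because the joint rule is already far
more conservative than any single criterion and this is how published
screens using these four algorithms operate. The null-cohort property test
(below) quantifies that conservatism empirically.

Numerical choices worth stating:

- **Zero cells.** ROR, PRR and EBGM are undefined when a margin cell is 0;
  the Haldane–Anscombe correction (+0.5 on all four cells) is applied *only
  to tables that need it*, and those rows carry `corrected = TRUE`. The IC
  needs no correction — its +0.5 shrinkage handles `a = 0` by construction.
- **χ² without continuity correction** by default; Yates is a flag. On the
  counts where the PRR criterion matters (χ² near 4, i.e. small tables) the
  choice is visible, so it is exposed rather than hidden.
- **The IC credibility offset** is a closed-form approximation to the
  posterior 2.5% quantile as a function of the observed count alone. We
  adopted it after verifying that it reproduces the printed `IC (IC025)`
  pairs of reference screens to the 2 decimals they print across the range
  `a ≈ 850–3400`; that arithmetic is frozen in the acceptance tests.
- **Two EBGM variants.** The default is the closed-form relative reporting
  ratio `a/E` with a log-normal lower bound — transparent, and equal to
  published EBGM columns to printed precision whenever shrinkage is weak
  (large `a`). The rigorous variant fits the DuMouchel-style two-component
  gamma mixture prior on `λ` by maximising the negative-binomial mixture
  marginal likelihood over all screened tables (`mgps_fit()`, BFGS on log /
  logit transforms from the conventional start (0.2, 0.1, 2, 4, 1/3)), and
  reports the posterior geometric mean and 5th percentile (`ebgm_full()`).
  Tests pin the posterior quantile against numerical integration of the
  mixture density, and check that shrinkage always moves estimates toward
  the null and vanishes as counts grow.
- **Rounding** for report output is half-up at 2 decimals (regulatory-table
  convention), via `round_half_up()`; R's banker's rounding would disagree
  on exact halves.
- `min_count` defaults to 3 — the conventional "at least 3 cases" floor
  below which no disproportionality estimate is taken seriously.

## Time-to-onset and the Weibull shape test

Onset is the event date minus the earliest day-precision therapy start
date, in whole days. Month- or year-precision (`YYYYMM` / `YYYY`) dates
carry no usable day, so those cases are excluded *and counted*, as are
missing/invalid dates and reversed pairs (event before start — an input
error); same-day onsets (TTO = 0) are retained. An accounting identity —
candidates = included + partial + reversed + missing — is asserted in the
tests so no case can vanish silently. When several therapy rows exist the
earliest complete start is used; a "latest start not after the event" rule
is available behind a flag, since the data do not say which therapy episode
caused the event. A case contributes its onset to every SOC it reports,
plus the pooled group, so per-group sample sizes overlap by design.

The onset distribution is summarised by quartiles (linear interpolation
between order statistics — stated because IQR endpoints depend on the
convention), 30-day bins with half-up percentages, and the cumulative
curve. A two-parameter Weibull is then fitted by maximum likelihood on
(ln α, ln β) with Wald 95% intervals from the observed information,
exponentiated back. The Weibull density needs strictly positive support,
so zero-day onsets are mapped to 0.5 days *inside the fit only* — the
choice is a documented convention, configurable via `zero_adjust`, and a
test verifies that changing it changes the fit (i.e. zeros genuinely
enter). Fits refuse degenerate inputs (n < 10, all-equal values) with
explicit errors rather than returning nonsense.

The shape β classifies the hazard profile: CI entirely below 1 → *early
failure* (risk concentrated just after the start of therapy, decreasing
thereafter), entirely above 1 → *wear-out*, spanning 1 → *random*. Recovery
tests sweep β ∈ {0.3, 1.0, 2.5} × α ∈ {10, 50} at n = 1000 over 20 seeds
and require ≥ 85% CI coverage and ≥ 18/20 correct classifications away
from β = 1.

## What the synthetic generator emulates — and what it does not

`simulate_reports()` produces the six raw tables with FAERS column names
and realistic pathologies, under one seeded generator whose draws are
consumed in a fixed documented order (target assignment, per-term
Bernoulli draws, onsets, start dates, demographics, concomitant drugs,
outcomes, pathology injection), so outputs are byte-reproducible.

Default study conditions, chosen once: 5,000 cases, 10% target-drug share,
a 24-term catalogue with per-term baselines of 0.3–4.5% (the order seen for
common terms in spontaneous databases), three planted associations at true
reporting-rate ratios 8, 5 and 2, onset Weibull scale 16.57 days / shape
0.28 (an early-failure profile typical of oncology-drug screens), 5%
duplicate versions, 1% deleted cases, 10% partial start dates, 2% reversed
date pairs, 10% missing event dates. A case that draws no catalogue term
receives the filler reaction "Drug ineffective" — by the same rule in both
arms, so planted rate ratios are untouched; with a small catalogue this
filler is common, which mirrors the real long tail of dictionary terms the
catalogue does not model. Event dates are start + round(Weibull draw), so
same-day onsets arise naturally. The generator returns a ground-truth
audit (injected duplicate/deleted/partial/reversed counts, true ratios,
true onset parameters) that downstream tests reconcile exactly.

It does **not** emulate: reporting dynamics over calendar quarters,
drug–drug interaction structure, dose fields, correlated event clusters
within a report beyond independent Bernoulli draws, or secular trends in
reporting. Passing tests therefore demonstrate that the pipeline recovers
known structure from FAERS-*shaped* data; they say nothing about
confounding, under-reporting or notoriety bias in real data, which no
disproportionality method can fix.

## Problem sizes used by the test suite

The property tests run at sizes chosen to make their statistical
assertions meaningful on one CPU: 1,000 random tables for the
oracle-equivalence sweep (tolerance 1e-10 relative); a null cohort of
6,000 cases × 250 terms for the false-signal bound (joint-rule signal
fraction ≤ 5% when every true ratio is 1); twenty replicate cohorts of
110,000 cases at 2% target share for estimator recovery (geometric mean of
ROR, PRR and EBGM within ±25% of planted ratios 2, 5, 10 at observed
counts ≥ 50 — the small share matters, because the closed-form EBGM's
expected count includes the target drug's own reports and compresses
visibly when the drug dominates the database); and 2 × 20 Weibull fits at
n = 1,000 for shape recovery. Full-scale published screens (thousands of
terms over millions of reports) are supported by the same code paths but
are not part of the test conditions.

## Known limitations

- Deduplication implements the stated rule (highest `PRIMARYID`, deleted
  list); manual case review performed in published screens cannot be
  reproduced algorithmically.
- The closed-form EBGM is a deliberate simplification; when the target
  drug is a non-trivial share of the database it under-shrinks relative to
  `a/E` interpretation (see above) and the MGPS variant should be used.
- Wald intervals on log-parameters are first-order; profile-likelihood
  intervals would widen slightly at small n.
- Percentages use each block's available denominator, so blocks are not
  comparable to each other without consulting their `available_n`.
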