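---
title: "Disproportionality signal detection for spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsignal)
```

## The problem

Spontaneous reporting systems (SRSs) such as FAERS, JADER and CVARD collect
voluntarily submitted individual case safety reports (ICSRs) of suspected
adverse drug reactions. They have no denominator of exposed patients, so the
standard analytic device is the *case-noncase* (disproportionality) design:
for a drug-event pair, reports are cross-classified into a 2x2 table

|                | index event | other events |
|----------------|-------------|--------------|
| **index drug** | a           | b            |
| **other drugs**| c           | d            |

and the question is whether the event is reported *disproportionately* often
with the index drug relative to the background of all other reports in the
same database. A disproportionality signal is hypothesis-generating, never
causal: reporting behaviour, media attention, channelling and confounding by
co-medication all move these statistics.

`srsignal` implements the full multi-database workflow around this design:
ingestion of FAERS-style relational extracts and flat single-table extracts
into one report schema, key-based deduplication, healthcare-professional
(HCP) and primary-suspect restriction, preferred-term (PT) classification
against a curated event set, four disproportionality statistics with a
combined positivity rule, a co-medication sensitivity rerun, cross-database
replication scoring, time-to-onset and reporting-trend summaries, and
labeling-gap classification. A seeded synthetic-SRS generator with analytic
expected cell counts makes every stage testable without external downloads.

## The four statistics and the combined rule

All four operate on the report-level 2x2 table (class-level pooled tables
may instead count (report, PT) occurrence pairs, matching the convention of
published validation tables in which one report can contribute several PTs).

**Reporting odds ratio.** `ROR = (a d)/(b c)` with the Wald interval
`exp(log ROR ± z sqrt(1/a + 1/b + 1/c + 1/d))`, `z = 1.96` by default. Any
zero cell triggers the Haldane–Anscombe correction (+0.5 on all four cells),
flagged in the output.

**Proportional reporting ratio.** `PRR = [a/(a+b)] / [c/(c+d)]`, accompanied
by the Pearson chi-square of the table. The chi-square uses the Yates
continuity correction by default — the common convention for the
`PRR >= 2 & chi2 >= 4` criterion — with a flag to disable it; the
uncorrected statistic is validated against `stats::chisq.test` in the test
suite.

**Information component.** The modern observed/expected shrinkage form:
with `E = (a+b)(a+c)/N`,

```
IC    = log2( (a + 0.5) / (E + 0.5) )
IC025 = log2 of the 2.5th percentile of Gamma(shape = a + 0.5, rate = E + 0.5)
```

The +0.5 terms shrink small counts towards the null; the credibility bound
comes from the gamma posterior on the rate ratio rather than the early
network formulation. This is the variant in contemporary use, and its
quantile is cross-checked against Monte-Carlo posterior sampling in the
tests.

**Gamma-Poisson shrinker (MGPS).** DuMouchel's empirical-Bayes model: each
cell's rate ratio `lambda` is drawn from a two-component gamma mixture
`w Gamma(alpha1, beta1) + (1-w) Gamma(alpha2, beta2)`, so the observed count
is marginally a mixture of negative binomials given `E`. The five
hyperparameters are fitted by maximizing the marginal likelihood over all
drug-PT cells of the database (cells with at least one co-occurrence by
default, no covariate stratification). The posterior for a cell is again a
gamma mixture; `EBGM = 2^(E[log2 lambda | a])` via the digamma function and
`EBGM05` is the 5th posterior percentile found by monotone root-finding on
the mixture CDF to 1e-8.

The combined rule declares a pair **positive** only when all four algorithms
pass: ROR lower 95% bound > 1; `PRR >= 2` with `chi2 >= 4`; `IC025 > 0`;
`EBGM05 >= 2`; and the pair has at least 3 co-occurrence reports. Pairs
below the floor are **not evaluable** and no statistics are reported for
them. No multiplicity adjustment is applied, consistent with the
hypothesis-generating setting. Because published class-level validation
tables are sometimes judged on the ROR alone, results carry both the
four-algorithm `status` and a `status_ror` column.

Two conventions here were genuinely open and are worth stating explicitly:

* **EBGM05 percentile.** "Lower one-sided 90% credibility interval" can be
  read as the 10th percentile; the MGPS literature and tooling
  overwhelmingly report the 5th. The default is the 5th
  (`eb_quantile = 0.05`), configurable.
* **EBGM05 threshold.** The rule uses `>= 2`; a strict `> 2` reading exists
  in some footnotes. Configurable via `signal_thresholds()`.

## Fitting the mixture prior

The marginal likelihood of a two-gamma mixture is multi-modal: a dominant
near-null bulk can absorb both components, hiding a rare high-ratio
component behind a local optimum (both components collapse onto the bulk
and the fitted prior becomes a near point mass at 1, which then shrinks
every posterior to 1). `fit_mgps_prior()` therefore runs EM from several
deterministic starting points — including heavily null-weighted starts with
a dispersed high-mean second component — and keeps the best likelihood,
finishing with a joint quasi-Newton polish accepted only when it improves
the likelihood, so the reported trace is non-decreasing end to end.

Large databases are fitted after *cell squashing*: cells with the same
observed count and similar `E` are merged into weighted points (counts above
50 stay exact). This is the standard device for gamma-Poisson shrinker fits
at scale and is what keeps the 50,000-cell parameter-recovery check in the
test suite inside a few minutes on one core.

One caveat the synthetic experiments make visible: in a database whose cells
are truly homogeneous (`lambda = 1` everywhere except an injected pair), the
maximum-likelihood prior is legitimately close to a pair of point masses.
Such a prior evaluates sensibly on cells of the universe it was fitted on,
but an *aggregated* exposure (e.g. a drug-class cell) whose ratio falls
between the spikes can be shrunk unpredictably. The practical rule, followed
by `compute_signals()`, is to evaluate EBGM on the same exposure definition
whose cells informed the prior; real, heterogeneous databases do not produce
spike priors and are insensitive to this.

## Ingestion, deduplication, filters

FAERS-style extracts arrive as `$`-delimited relational tables (DEMO, DRUG,
REAC, optional OUTC/THER); JADER- and CVARD-style extracts as one flat CSV
per database with one row per (report, drug, event). Both are assembled into
one relational report schema keyed by `report_id`.

* **Deduplication** is key-based: FAERS versions share a case id and the
  latest receipt date wins, with receipt-date ties broken by the
  lexicographically largest report id (deterministic; the upstream guidance
  is silent on ties). Flat extracts key on their unique report id. A
  DELETED-list mechanism removes ids before keying. The operation is
  idempotent and is tested against a brute-force group-by/argmax oracle.
* **Inclusion filters** drop records flagged invalid at assembly (no drug or
  no event) and all non-HCP reports. Whether the HCP restriction applies to
  the comparator background as well as the exposed series is ambiguous in
  parts of the applied literature; it is applied to **both** here
  (symmetric design), so exposed and background reports come from the same
  reporter population.
* **Dates** are parsed at their native precision (`YYYYMMDD`, `YYYYMM` with
  the day imputed to the 15th, `YYYY` to July 1). Partial dates are usable
  for annual trends but never for time-to-onset, which requires full day
  precision on both therapy start and event date.
* **Drug names** are matched exactly after lowercasing and stripping
  non-alphanumerics; no fuzzy matching (reproducibility over recall).
  Unmatched mentions keep a null drug id and never count as exposure.
* **Ages** are converted to years from the FAERS unit codes; the age bins
  (`<2`, `2-11`, `12-17`, `18-64`, `65-85`, `>85`, closed on the left) match
  the descriptive-table convention.

Every stage logs input/output counts; the attrition table reconciles
exactly (each removed report is attributed to exactly one stage).

## Temporal and descriptive summaries

Time-to-onset is `event_date - earliest therapy start` of the index drug's
primary-suspect mention (first exposure when several starts exist);
same-day onset counts as 0 days and negative deltas are non-evaluable.
Summaries use type-7 (linear interpolation) quantiles, and the ECDF is
reported on an integer-day grid. Annual trends count classified cases by
receipt year by default (event year optional; the basis is not universally
standardized). Seriousness proportions use each drug's case count as the
denominator and flag denominators below 20, where a single report moves the
percentage by 5 points or more.

## Cross-database replication and labeling gaps

Each PT gets a per-database count of positive algorithms (0–4, `NA` when
below the co-occurrence floor or absent), ordered by replication strength.
A discovery signal is *replicated* when ROR > 1 with the interval excluding
unity in at least two databases — the discovery database counts towards the
two, so discovery plus one independent confirmation suffices. PTs evaluable
nowhere are reported as not evaluable, never as failed replication.

Label concordance classifies each four-algorithm-positive (drug, PT) as
`known` (present in the drug's prescribing-information map) or `new_signal`;
a third `labeled_not_detected` category is kept for completeness but
excluded from the standard stacked counts. The PI-to-PT map is a curated
input file; the package never parses label documents.

## The synthetic-SRS generator

The generator exists so that every pipeline stage can be validated against
known ground truth. Its default configuration emulates the structure of the
study databases at desk scale: a small set of low-exposure study drugs
(antibody–drug-conjugate-like agents) against a common-drug background;
rare target PTs against common background PTs; report-level missingness of
roughly the magnitude seen in public descriptive tables (30% missing age,
12% missing sex, 25% missing therapy dates, 10% month-precision dates, 5%
unresolvable drug names); a reporter mix with 20% consumer reports (removed
by the HCP filter); ~1 + Poisson(1.5) events per report; 10% superseded
duplicate versions; and per-drug log-normal onset delays (median 30 days,
`sdlog` 0.8).

The event model is the key design choice: each PT enters a report of drug
`g` independently with probability `min(1, s * base_prob * rho(g, pt))`,
where `s` calibrates the expected number of events per report and `rho` is
the injected relative reporting rate; the draw is conditioned on at least
one event per report (rejection). Conditioning keeps every inclusion
probability in closed form — `P(pt present) = q / (1 - prod(1 - q))` — so
`expected_cells()` returns analytic a/b/c/d expectations and the *implied*
true odds ratio for every pair. That implied odds ratio, not the raw
multiplier `rho`, is the recovery truth for calibration and coverage
checks: the cap, the conditioning and dictionary misses all shift the
report-level odds ratio away from `rho`, and the analytic form accounts for
all three. The confounding scenario attaches the elevated rate only to
reports carrying a neurotoxic co-medication, so excluding those reports
removes the association — reproducing the qualitative signal-loss pattern
of a co-medication sensitivity analysis.

What the generator does **not** emulate: real co-prescription networks,
drug-specific reporting waves, MedDRA coding noise, country-specific
reporting cultures, or record-linkage-level duplication (duplicates share a
key by construction). Passing tests therefore demonstrate algorithmic
correctness and statistical calibration under a known model — not that any
particular real-world signal is true.

## Problem sizes and numerical choices in the test suite

The suite validates, among others: exact reproduction of published
class-level validation tables (three databases); IC025/EBGM/EB05 against
Monte-Carlo posterior sampling (2x10^5–5x10^5 draws, ±0.02 on the log2
scale and 1% relative respectively); recovery of a known two-gamma prior
from 50,000 simulated cells to within 10% per hyperparameter (the truth —
`w = 0.9` on a null-like `Gamma(1.2, 1.2)` plus a dispersed signal
component `Gamma(2, 0.25)` with cell expectations spanning roughly 0.4 to
50 — is a well-separated, realistic configuration; heavily overlapping
mixtures are not identifiable to 10% at this sample size and no fitter can
make them so); null calibration of the ROR interval over 4,800 drug-PT
pairs pooled from four 50,000-report null cohorts (4–6% of 95% intervals
excluding 1); detection power on a single injected `rho = 8` pair at 50,000
reports; and 94–95% empirical coverage of the analytic true odds ratio over
1,000 replicate 1,500-report cohorts.

Fixed seeds make these checks reproducible; none of the tolerances is
tuned to a particular draw. Root-finding for posterior quantiles uses
`uniroot` to 1e-8 with brackets from the component quantiles; EM
convergence requires likelihood improvements below 1e-8 for three
consecutive iterations or 500 iterations, followed by the quasi-Newton
polish.

## Known limitations

* No stratified MGPS (age/sex/year strata) and no regression-based signal
  detection; the comparator is always the whole-database background.
* Deduplication is key-based only; probabilistic record linkage across
  differently-keyed versions is out of scope.
* The packaged PT list is a documented stand-in (the licensed vocabulary's
  curated list is a drop-in CSV with the same columns); packaged label maps
  are synthetic illustrations.
* Class-level pooled tables inherit the exposure-aggregation caveat for
  EBGM described above.
* Annual trends use receipt year by default; event-year trends differ when
  reporting lags are long.
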