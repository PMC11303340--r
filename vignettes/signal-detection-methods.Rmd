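---
title: "Disproportionality signal detection on FAERS spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on FAERS spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersig)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect individual case safety reports (ICSRs)
submitted by consumers, clinicians and manufacturers. They have no
denominator — nobody knows how many patients took a drug without incident —
so drug safety signals are screened by *disproportionality*: is adverse
event $E$ reported more often with drug $D$ than the rest of the database
would predict? `faersig` implements the full screening workflow for FAERS
quarterly ASCII extracts: ingestion, case-level curation, primary-suspect
cohort construction, four disproportionality statistics at the MedDRA
preferred-term (PT) and system-organ-class (SOC) levels, time-to-onset
analysis, and a deterministic synthetic-data generator with planted signals
for validation.

## Curation model

FAERS distributes every *revision* of a case, so one CASEID may appear under
several PRIMARYIDs across quarters. Following the FDA-recommended rule,
`deduplicate_reports()` keeps, per CASEID, the record with the highest
FDA_DT, breaking ties by the highest PRIMARYID (numeric comparison when the
id parses as a number, FAERS practice; else lexicographic). Since 2019Q1
each quarterly packet also carries a roster of deleted cases;
`apply_deletions()` removes those CASEIDs *after* deduplication, matching
the published order of operations. FDA_DT values may be partial (`YYYY`,
`YYYYMM`, `YYYYMMDD`); ordering uses the deterministic key
(year, month-or-0, day-or-0), so a partial date never outranks a fuller date
in the same period.

The study cohort is selected by whole-token name matching on DRUGNAME and
PROD_AI after normalisation (case folding, trademark-glyph stripping,
whitespace collapsing, punctuation treated as token separators). So
`"SUNITINIB MALATE"` and `"Sutent®"` match a `{sunitinib, sutent}` cohort
while `"nilotinib"` does not. The default role restriction is PS (primary
suspect). Non-DEMO rows whose PRIMARYID is missing from DEMO are retained
with an `orphan` flag rather than dropped: deduplication operates on DEMO
and joins later, and dropping early would silently change counts.

MedDRA itself is licensed and cannot ship with the package; `read_vocab()`
accepts any two-column PT→SOC TSV, and a small synthetic vocabulary is
bundled for examples and tests.

## The four statistics

For one drug and one term, with the unique (report, term) pair as counting
unit,

|            | term  | other terms |
|------------|-------|-------------|
| drug       | $a$   | $b$         |
| other drugs| $c$   | $d$         |

and $N = a+b+c+d$, the package computes

* **ROR** $= ad/bc$ with the Woolf interval
  $\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$;
  criterion: CI lower bound $> 1$ and $N \ge 3$.
* **PRR** $= \frac{a/(a+b)}{c/(c+d)}$ with the Pearson $\chi^2$ statistic
  $N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))$, no continuity correction;
  criterion: PRR $\ge 2$, $\chi^2 \ge 4$, $N \ge 3$.
* **IC** $= \log_2 \frac{aN}{(a+b)(a+c)}$, the BCPNN information component;
  criterion: IC025 $> 0$ (strict).
* **EBGM** $= \frac{aN}{(a+b)(a+c)}$ with
  EBGM05 $= \exp(\ln \mathrm{EBGM} - 1.96\sqrt{1/a+1/b+1/c+1/d})$;
  criterion: EBGM05 $> 2$, $N > 0$.

Two deliberate design choices deserve emphasis.

**EBGM is the unshrunk relative reporting ratio.** As implemented (and as
tabulated in the screening literature this package follows), EBGM is
identically $2^{\mathrm{IC}}$ — one statistic on two scales — and the
package asserts that identity on every computed row. Full gamma-Poisson
mixture (MGPS) shrinkage, which would pull small-count estimates toward 1,
is intentionally out of scope; the $N$-based criteria already guard the
small-count regime, and the unshrunk form is what the four-way criterion
framework expects.

**IC025 is a seeded Monte-Carlo credible bound.** A Woolf-type interval on
the $\log_2$ scale would be far too narrow for small $a$ compared with the
Bayesian intervals the BCPNN formulation uses. `compute_ic()` draws the
observed count from a $\mathrm{Gamma}(a + \tfrac12, 1)$ posterior, divides
by the expected count $E = (a+b)(a+c)/N + 1/(2N)$, and reports the 2.5%
quantile of $\log_2(\lambda/E)$ over `mc_draws` draws (default $10^5$,
seeded, caller RNG state preserved). This is an approximation: exact
reproduction of any particular published IC025 value is not claimed, and
nothing in the test suite asserts one.

**Counting unit.** A report contributes once per distinct PT, and once per
distinct SOC at SOC level, so SOC-level totals exceed the report count —
consistent with published SOC tables whose event totals are several times
the cohort size. The background is the entire curated database minus the
cohort.

**Degenerate tables.** Any zero cell leaves at least one estimator or
interval undefined, so such tables are flagged `degenerate` and excluded
from scoring (every flag false). An optional additive continuity correction
(`continuity = 0.5`) rescues them when explicitly requested; it is off by
default because the canonical formulas carry no correction. The BCPNN flag
is IC025 alone by default; `bcpnn_strict = TRUE` additionally requires the
PRR conditions for screens that use the conjunctive form.

**Rankings.** `rank_signals()` keeps terms positive on all four criteria
and sorts by report count ("frequency") or ROR, with deterministic
tie-breaks (the other key descending, then term). `flag_unexpected()` marks
terms absent from a user-supplied drug-label PT list.

## Time to onset

Onset is the day difference between the event date and the earliest
full-precision therapy start date linked to the cohort drug (by drug
sequence number when both sides carry one, else any therapy row of the
report). Same-day onset (0 days) is kept; only strictly negative intervals
are treated as erroneous. Records are excluded — with reasons
(`missing_event`, `missing_start`, `partial_date`, `negative`) that
partition the cohort — when either date is absent or below day precision.
Quartiles use linear interpolation between order statistics (R's default
type 7; the convention is configurable in spirit but deliberately fixed for
determinism). Bins are half-open $[lo, hi)$ with 30-day "months" up to 180
days, then 180–359, then $\ge 360$ ("after one year" under the
30-day-month convention; an exact-365 convention can be had by passing
custom `bin_edges`).

## The synthetic generator

`generate_faers()` produces multi-quarter bundles in the exact file dialect
the parser reads, with known ground truth. Per report: one primary-suspect
drug drawn by prevalence (remaining probability mass split across five
background comparator drugs); a PT set drawn by independent per-PT
Bernoulli trials at `baseline_prob` times the planted relative reporting
rate `rr` when the drug carries a planted signal; demographics from
categorical marginals; therapy start, event and receipt dates consistent
with a log-normal onset distribution. A configured fraction of cases is
re-emitted in a later quarter with a later FDA_DT and higher PRIMARYID
(revisions), and a fraction is listed on the final quarter's deleted
roster. Generation is fully deterministic given the seed.

Defaults are the package's reference study conditions: 20,000 reports over
eight quarters, a sunitinib-like focal drug at 5% prevalence, a 20-PT
panel, planted rates on five hallmark adverse events (diarrhoea 2.8,
dysgeusia 9.2, hypothyroidism 8.8, hand-foot syndrome 25, yellow skin 60),
sex/age/country/reporter marginals matching the published descriptive
profile of sunitinib reports (male 59.35%, age ≥ 65 38.55%, US 48.87%,
consumer 38.13%), and onset log-normal with median 51 days and IQR
≈ 16–170 days ($\mu = \ln 51$,
$\sigma = (\ln 170 - \ln 16)/(2 \times 0.6745)$) — a stylised match to the
published onset profile, not a fit. A quarter of event dates are degraded
to year-month precision or blanked and 30% of therapy starts are missing,
so roughly half the cohort is onset-eligible, in line with real FAERS
completeness.

What the generator does *not* emulate: polypharmacy (one suspect drug per
report keeps the truth tables closed-form), co-reporting correlation
between events, temporal reporting trends, and the guarantee that every
report has at least one reaction (the PT set may be empty; forcing a
minimum would bias the planted rates away from their closed-form
expectations). Passing tests therefore demonstrate correctness of the
pipeline's logic and calibration of the estimators under an idealised
reporting model — not that any particular real-world signal is genuine.

## Validation conditions

Two simulation suites validate the statistics end to end.

**Null calibration.** With all `rr = 1`, across 20 replicates of 5,000
reports, at most 10% of terms with $a \ge 3$ may be ROR-flagged — the
one-sided 2.5% nominal behaviour of the CI criterion leaves comfortable
margin.

**Planted-signal recovery.** For `rr` in {2, 5, 10} the planted rate must
fall within the ROR and EBGM 95% intervals in at least 90% of 50
replicates. The conditions mirror spontaneous-reporting scale: drug
prevalence $0.02/rr$ (0.2–1% of the database — real cohorts are this
sparse; sunitinib is ≈ 0.17% of FAERS), target baseline $0.05/rr$ against
six common events of total mass 1.2 per report, and $n = 30{,}000 \times
rr$ so the expected signal count is 30. The scaling is dictated by a
closed-form attenuation analysis: the EBGM is a relative reporting *rate*
ratio, bounded above by the reciprocal of the drug's prevalence and
attenuated by the factor $[1 + B(rr-1)/S] \times [1 + p(rr-1)]$ (cohort
event-mass inflation times term-margin inflation, with $B$ the target
baseline, $S$ the total event mass, $p$ the prevalence). At 50% prevalence
the estimand itself sits below 2 regardless of `rr` — no estimator defect,
just what the statistic measures — whereas at the chosen conditions both
attenuation factors stay under ~4%, well inside the Woolf interval's width
at $a = 30$. The ROR, an odds ratio conditioned on the drug, is unaffected
by this attenuation.

## Numerical and engineering choices

* IDs stay strings end to end (FAERS PRIMARYIDs overflow 32-bit integers
  and may carry leading zeros); contingency arithmetic is done in doubles.
* Files are "$"-delimited with a header; rows with the wrong field count or
  out-of-vocabulary codes are dropped and counted, and
  `rows_in = rows_kept + rows_dropped` holds per table. Encoding is UTF-8
  with per-file Latin-1 fallback. Legacy column layouts (e.g. ISR-keyed
  LAERS extracts) are handled by dialect column overrides.
* Ages are normalised to years from AGE_COD (months /12, weeks /52.18,
  days /365.25, decades ×10, hours /8766) before banding at
  <18 / 18–44 / 45–64 / ≥65 / unknown. Outcome percentages use the total
  cohort-report denominator; one report may carry several outcome codes,
  each counted once per report.
* All randomness (generator, IC Monte-Carlo) runs under locally scoped
  seeds that restore the caller's RNG state, so reruns with one
  configuration are byte-identical.
* Problem sizes in the test-suite simulations (reference studies of
  1,200–20,000 reports; recovery replicates up to 300,000) were chosen as
  the smallest sizes at which the validated properties are identifiable
  with comfortable margin.

## Known limitations

* EBGM carries no empirical-Bayes shrinkage; small-count estimates are
  noisy and rely on the $N \ge 3$ criteria for protection.
* IC025 is Monte-Carlo, not the closed-form BCPNN posterior moments;
  published IC025 values from other implementations will differ slightly.
* Name matching is exact whole-token; misspelled drug names in real FAERS
  data are missed (no fuzzy matching, RxNorm or ATC mapping).
* The vocabulary maps each PT to a single (primary) SOC; MedDRA
  multi-axiality and LLT→PT roll-up are out of scope.
* No multiple-comparison adjustment is applied across terms, matching
  standard practice for hypothesis-generating screens; results are signals
  for follow-up, not confirmed associations.
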