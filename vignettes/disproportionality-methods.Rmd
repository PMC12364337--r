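---
title: "Reporting-odds-ratio signal detection on FAERS-style spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporting-odds-ratio signal detection on FAERS-style spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect voluntary reports of suspected drug–event
pairs. They have no denominator — nobody knows how many patients took a
drug without an event being reported — so absolute risks cannot be
estimated. What *can* be estimated is disproportionality: whether a given
event is reported more often with a given drug than with everything else
in the database. `faersignal` implements this analysis end to end for the
FAERS quarterly ASCII dialect, with a synthetic report generator so every
stage can be validated against known ground truth.

The shipped example configuration targets the five anaplastic lymphoma
kinase (ALK) inhibitors used in ALK-rearranged cancers — crizotinib,
ceritinib, alectinib, brigatinib, lorlatinib — and two cardiopulmonary
adverse events of clinical concern with these agents, the MedDRA
preferred terms *Pleural effusion* and *Pericardial effusion*. The design
generalizes to any drug/event grid supplied in the run configuration.

## The statistic

For one (drug, event) pair the cleaned report collection is
cross-classified into a 2×2 table of report counts:

|            | event | no event |
|------------|-------|----------|
| drug       | a     | b        |
| other drugs| c     | d        |

The reporting odds ratio is

$$\mathrm{ROR} = \frac{a\,d}{b\,c},$$

with the Woolf (log-normal) confidence interval

$$\mathrm{SE}(\ln \mathrm{ROR}) = \sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d},
\qquad
\mathrm{CI}_{95} = \exp\!\left(\ln \mathrm{ROR} \pm z_{0.975}\,\mathrm{SE}\right),$$

with $z_{0.975} = 1.959964$. The interval is symmetric on the log scale,
so the point estimate is the geometric mean of its bounds — a property
`implied_ror_from_ci()` exploits to audit published tables that print
only rounded bounds. The Woolf construction was adopted because it is
the standard ROR interval in pharmacovigilance practice and because every
row of the shipped reference table satisfies its log-symmetry to within
two-decimal rounding of the bounds (eight of ten rows round exactly; the
two others agree within 0.02, test `test-acceptance.R` exercises this).

**Zero cells.** If any cell is zero the Haldane–Anscombe correction adds
0.5 to all four cells before computing, and the result carries
`corrected = TRUE`. `n_reports` always reports the uncorrected `a`. An
all-zero table is an error, never a silent `NaN`.

**Signal rule.** A pair is flagged a signal when all three hold:
ROR strictly greater than 2.00, lower 95% bound strictly greater than
1.00, and at least 10 drug-and-event reports. The strict inequalities
follow the conventional wording "exceeding 2.00" / "above 1.00"; the
report-count criterion is `>=`. No multiple-testing adjustment is
applied: the tri-criteria rule is itself the guard against false
positives, and under a null simulation the flag rate is well below 2.5%
(the one-sided level of the CI criterion alone).

## Cleaning model

FAERS quarters arrive as `$`-delimited DEMO/DRUG/REAC files
(primaryid-era schema, 2012Q4 onward; the legacy ISR schema is out of
scope). Cleaning proceeds in counted stages, and every stage appends a
`(stage, reports_in, reports_out)` row to the series' provenance chain,
which must telescope and be monotone non-increasing:

1. **read/merge** — rows that cannot be parsed (wrong field count,
   missing keys, invalid role codes, duplicate preferred terms within a
   report) are rejected and counted by reason, never silently dropped;
   `rows_read = rows_kept + rows_rejected` holds per file. A
   `primaryid` resubmitted in a later quarter supersedes the earlier
   occurrence.
2. **deduplicate** — one case may generate several report versions; for
   each `caseid` exactly one survives: highest `caseversion`, ties
   broken by latest FDA receipt date, then by greatest `primaryid`.
   Deduplication is idempotent.
3. **window** — reports are filtered on the FDA receipt date (`fda_dt`)
   to an inclusive window, by default 2013-01-01 to 2023-12-31. FAERS
   offers several candidate date fields; the receipt date is used
   because it is populated for essentially all reports and is the field
   the quarterly release cycle is organized around. Truncated dates
   (`YYYYMM`, `YYYY`) resolve to the first day of the period;
   unresolvable dates exclude the report from windowed analyses and are
   counted.

**Drug matching.** Verbatim drug names are normalized (uppercase, trim,
collapse whitespace, strip punctuation except hyphens — idempotent and
case-insensitive), then matched against per-drug synonym maps by *token
containment*: `XALKORI CRIZOTINIB 250MG` matches canonical CRIZOTINIB
via either the brand or the generic token, but `IMATINIB` does not match
a `TINIB` fragment. Both the verbatim name and the active-ingredient
field are searched. With the primary-suspect restriction (the default),
the matching entry must carry role code `PS`, which strengthens the
attribution of the event to the drug. A report counts once however many
of its drug entries match.

**Event matching** is case-insensitive exact equality on trimmed MedDRA
preferred terms, treated as plain strings; the licensed MedDRA hierarchy
(LLT→PT, SOC rollups) is out of scope.

## The synthetic generator

`generate_reports()` produces FAERS-shaped populations with known ground
truth. Per case: independent Bernoulli exposures to each target drug at
its marginal probability; event occurrences at background probability
$p_0$, overridden for injected (drug, event) pairs by the inverse-odds
construction

$$p_1 = \frac{\mathrm{OR}\cdot p_0}{1 - p_0 + \mathrm{OR}\cdot p_0},$$

so the population odds ratio equals the injected target exactly. Role
codes default to `PS` with a configurable fraction demoted to `SS`/`C`
(demotion is independent of event status, so the primary-suspect
restriction thins the exposed arm without biasing the OR). A configurable
fraction of cases is emitted with two versions differing only in
`caseversion`, `primaryid` and receipt date, so deduplication
correctness is testable by exact count. Every case carries one
background concomitant drug and one background reaction term, making
generated files parse with zero rejects and no flagged reports.

**Defaults as study conditions.** The defaults emulate the regime of an
ALK-inhibitor effusion analysis: five drugs at 1% marginal exposure,
pleural effusion at 1% and pericardial effusion at 0.5% background,
one injected association (crizotinib–pleural effusion, OR 8 — the
magnitude published effusion tables report), duplicate rate 0.1,
demotion rate 0.1, receipt dates uniform over 2013-01-01..2023-12-31.
At the default population size of 100,000 reports the injected pair's
`a` cell averages ≈ 67, inside the 18–150 range of published effusion
report counts. These values were fixed once, from the target regime, and
the validation suite runs against them.

**What the generator does not emulate:** drug co-prescription
correlation, demographic covariates, reporter-type effects,
masking/competition bias, secular reporting trends. Passing tests
demonstrate that the counting, cleaning and estimation machinery is
correct under the stated sampling model — not that real FAERS data meet
that model.

## Validation design and problem sizes

The suite validates each claim at the smallest size that makes the check
statistically meaningful:

- **Oracle equivalence** — on 100 randomized series (≤ 1,000 reports),
  the vectorized 2×2 construction must equal a deliberately naive
  per-report double loop exactly.
- **CI calibration** — 10,000 multinomial tables at true OR 3 with
  expected `a` ≈ 58: empirical 95% coverage must lie in [0.94, 0.96].
- **Type-I control** — 10,000 null tables (OR 1, expected `a` ≈ 12):
  signal-flag rate below 0.025.
- **Parameter recovery** — 200 generator seeds × 100,000 reports with
  OR 8 injected: the median pipeline ROR must lie within 5% of 8 and the
  95% CI must cover 8 in 0.95 ± 0.02 of seeds. (At `a` ≈ 67 the
  log-scale SE is ≈ 0.13, so the 200-seed median is a ≈ 1% measurement
  of the estimand.)
- **Empirical-OR convergence** — a one-million-report population with
  enriched exposure (10%) and event (5%) probabilities, where a 2%
  relative error corresponds to ≈ 2.4 standard errors of the empirical
  log-OR.
- **Determinism** — fixed seed ⇒ byte-identical quarter files and
  results CSV across independent runs, with zero rejected rows.

All stochastic checks enumerate fixed seeds. `scripts/acceptance.R`
recomputes the same quantities from scratch against the installed
package and writes them as JSON.

## Numerical and design choices

- ROR arithmetic is done in double precision from integer cells
  (products like $a \cdot d$ overflow 32-bit integers on large
  backgrounds).
- The dedup tie-break chain (version, date, `primaryid`) is total, so
  deduplication is deterministic for any input ordering; missing dates
  lose date tie-breaks.
- The `$` delimiter has no quoting convention in the FAERS dialect;
  on write, `$` characters are stripped from values, and the sanitized
  form round-trips stably.
- Input bytes are decoded as Latin-1 (FAERS files contain non-UTF-8
  bytes) and handled internally as UTF-8.
- Degenerate inputs: an empty DEMO body yields an empty series (not an
  error); an empty drug list yields an empty results table; an all-zero
  2×2 table is a per-row error carried in the results' `error` column
  without aborting other rows.
- The results CSV carries full precision; the plain-text report view
  rounds to two decimals, the conventional presentation in signal
  tables.

## Limitations

RORs measure reporting disproportionality, not incidence or causality;
they are vulnerable to under-reporting, stimulated reporting and
confounding by indication, none of which the package can correct. The
cleaning steps are documented, testable rules in the spirit of standard
FAERS preprocessing tools; they are not a byte-for-byte emulation of any
particular service, and published tables derived from a specific dated
snapshot through such a service will generally not be exactly
reproducible from other snapshots. The shipped reference table is
therefore used for internal-consistency auditing (log-symmetry,
interval-width plausibility), not for re-derivation.
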