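---
title: "Disproportionality signal detection on FAERS-style spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on FAERS-style spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(data.table)
```

## The problem

Spontaneous reporting systems such as the FDA Adverse Event Reporting
System (FAERS) collect voluntary reports of suspected adverse drug
reactions. They have no denominator of drug users, so drug safety signals
are sought by *disproportionality*: is an event reported more often with
the target drug than the rest of the database would predict? `faersignal`
implements this workflow for FAERS-style quarterly ASCII extracts, with
edaravone — a free-radical scavenger used in amyotrophic lateral sclerosis
(ALS) and acute ischemic stroke — as the worked target drug: its reference
mapping tables and published summary statistics ship with the package.

The pipeline is: ingest the six `$`-delimited tables (DEMO, DRUG, REAC,
OUTC, INDI, THER) → deduplicate report versions → standardize drug names
and map preferred terms (PTs) to system organ classes (SOCs) → build
drug-event 2×2 tables → compute ROR, PRR, chi-square and the BCPNN
information component → screen, rank, and stratify by sex → summarize
demographics, indications and the quarterly report stream.

## Data model and deduplication

Each FAERS case (CASEID) may appear as several report versions
(PRIMARYID) as follow-ups arrive. All analysis cells count *deduplicated
reports*: for each CASEID the version with the most recent FDA_DT is
kept, ties broken by the higher PRIMARYID. Deduplication runs across the
whole pooled multi-quarter extract, so a case revised in a later quarter
supersedes its earlier versions. PRIMARYIDs are compared numerically when
fully numeric (always true in FAERS practice), otherwise lexicographically
after zero-padding.

Rows that cannot be interpreted — blank primaryid, an invalid calendar
date, a satellite row whose primaryid has no DEMO row, a report with no
reaction rows — are *quarantined* with file/line diagnostics and counted,
never silently dropped; every load satisfies
`rows_in = rows_parsed + rows_quarantined`.

Partial dates (YYYYMM, YYYY) are padded to the first day/month so version
ordering stays total, and flagged imprecise. Ages convert to years by the
FAERS unit code (DEC ×10, YR ×1, MON ÷12, WK ÷52.14, DY ÷365.25,
HR ÷8766); an unknown unit leaves age missing.

**Time to onset** is not directly recorded. The package uses the proxy
`FDA_DT − earliest therapy start date`, computed only when both are full
dates and the start does not postdate the report; otherwise onset is
"Unknown". The onset denominator is reports with *any* therapy record,
which is what reconciles the published onset percentages with their
category counts. This proxy is a documented choice, not a FAERS field.

## Name and term mapping

NLP-based drug-name normalization is replaced by a deterministic synonym
dictionary (trim, case-fold, collapse whitespace, strip trailing
dosage/form tokens, look up). MedDRA is licensed, so the PT→SOC step is a
user-suppliable two-column table under the primary-SOC convention; the
bundled table covers the PTs of the reference analysis and the synthetic
catalog. Unmatched names return `UNMAPPED` / `UNMAPPED_SOC` and are
counted, so coverage is always `mapped + unmapped = total distinct names`.

A report counts as *exposed* only when some drug row is primary suspect
(role `PS`) and standardizes to the target. Whether secondary suspects
should count is genuinely open in this design; `roles = c("PS", "SS")`
switches it on, with PS-only the default because the reference pool is
defined by primary-suspect reports.

## The 2×2 table and the four statistics

For one drug and one event, over `N` stratum reports:

|            | event | no event |
|------------|-------|----------|
| drug       | a     | b        |
| no drug    | c     | d        |

The background (`c`, `d`) is the full database minus the exposed reports
(full-database comparator). Counting is per report: a report with the same
PT twice counts once, and a report with several distinct PTs enters
several PT-level tables, so `sum(a)` over PTs can exceed the exposed
count — by design.

- **ROR** `= ad/(bc)`, Woolf interval
  `exp(log ROR ± z·sqrt(1/a + 1/b + 1/c + 1/d))`.
- **PRR** `= [a/(a+b)] / [c/(c+d)]`, interval
  `exp(log PRR ± z·sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d)))`.
- **Chi-square**: Pearson `N(ad−bc)² / [(a+b)(c+d)(a+c)(b+d)]` by default;
  `yates = TRUE` subtracts `N/2` from `|ad−bc|` (floored at 0). The
  reference analysis does not say whether its chi-square was
  Yates-corrected; both ship, and the inversion audit (below) is the
  evidence either way.
- **BCPNN information component**, two variants:
  - `bate`: closed-form posterior moments of the original BCPNN with
    priors `α₁ = β₁ = 1`, `α = β = 2`, `γ₁₁ = 1` and
    `γ = γ₁₁(N+α)(N+β)/[(a+b+α₁)(a+c+β₁)]`;
    `IC025 = E(IC) − 2·sd(IC)`. On any balanced table `E(IC) = 0`
    exactly.
  - `oe_simple`: `IC = log2((a+0.5)/(E+0.5))` with `E = (a+b)(a+c)/N`,
    and `IC025 = IC − 3.3(a+0.5)^(−1/2) − 2(a+0.5)^(−3/2)`.

  `bate` is the package default, being the literature default behind
  "IC(IC025)" columns; the two agree asymptotically (checked at N = 10⁶
  to within 0.01).

**Zero cells.** When any cell is zero, ROR/PRR get the Haldane–Anscombe
+0.5 on all four cells and the row is flagged `corrected`; with the
correction disabled a zero cell yields an `NA` undefined-result marker,
never an error. Confidence intervals use `z = qnorm(0.975)` rather than a
rounded 1.96.

## Screening, ranking, stratification

A PT is screened only when `a ≥ 3` (the conventional minimum report
count). The three rules are `ror_lo > 1`; `prr ≥ 2` together with
`chisq ≥ 4`; and `ic025 > 0`. The default combination mode `"all"`
demands all three — cross-validation across methods to limit false
positives — with `"any"` available. Ranking is by descending `ror_lo`
(signal strength by CI lower bound) or by `a` (report number), ties
broken by `a` then PT alphabetical order, so output order is total and
reproducible.

Sex stratification recomputes *all four cells* within each stratum;
unknown-sex reports are excluded from both strata, so the two analyses
are computed on disjoint report sets. A stratum without exposed reports
returns an empty table with a warning.

At SOC level a report contributes once per SOC regardless of how many of
its PTs map there, and the information component is computed on the
SOC-level 2×2.

## Descriptive layer

`demographic_table()` reproduces the standard descriptive table: sex, age
band (<18, 18–45, 45–60, ≥60, Unknown), reporter occupation, country (top
two plus Other), route, outcomes, onset band (<7, 7–28, 28–60, ≥60 days,
Unknown), with `percent = round(100·count/denominator, 2)`. The
denominators are deliberately variable-specific: sex/age/reporter/country
percentages run over all reports, outcome percentages over reports with
an outcome record, onset percentages over reports with a therapy record.
These choices are reverse-engineered from the published table's own
numbers (e.g. 962 deaths / 1,734 outcome-specified reports = 55.48%) and
are the only denominators that reproduce all printed percentages.

Indication percentages are printed over indication *records*, since a
report can list several indications for the drug; the reference table's
own indication percentages use a denominator that cannot be reconstructed
from its printed counts, and the package does not chase it.

## The inversion audit

The published PT-level signal table prints, per term, the exposed count
`a`, ROR, PRR, chi-square and IC(IC025) — but not `b`, `c`, `d`, and the
full 2017Q2–2024Q2 FAERS extract needed to recompute them is far beyond
desk scale. `audit_signal_table()` therefore *inverts* each printed row:
with the known exposure margin (`a + b = 2931`), PRR fixes the implied
background odds `d/c`, and the printed chi-square then pins the scale,
solved for `c` by `uniroot` on a bracket where the chi-square is monotone
toward its finite large-`c` asymptote. ROR would fix `d/c` too, but after
rounding the two printed ratios are slightly inconsistent and the
ROR-derived ratio can push the printed chi-square above its attainable
asymptote; the PRR route is the numerically stable one, and the implied
ROR is reported back as a residual diagnostic. A row whose rounded
statistics admit no exact table is reported unsolved rather than forced.

On the implied tables the IC is recomputed under both BCPNN variants and
the absolute gap to the printed IC reported. This is a diagnostic of
which formula the reference analysis used — the gaps are computed by the
acceptance script at run time, never asserted to be zero.

## The synthetic generator

Real FAERS data cannot ship with the package, so every pipeline stage is
validated against a generator with known ground truth. Its defaults are
fixed once to mirror the composition of the reference pool: sex 40.7%
male / 27.2% female / rest unknown, 68.8% age missingness, the published
reporter / country / route / outcome distributions, ~59% of reports
carrying an outcome record, ~42% a therapy record (a third of them with a
full start date), quarters 2017Q2–2024Q2. The drug catalog makes the
target the primary suspect of 5% of reports; the PT catalog spans common
to rare terms (baselines 0.30 down to 0.002).

Reactions are independent Bernoulli draws per catalog PT; an injected
association `(drug, pt, ρ)` multiplies the exposed-arm probability to
`min(1, ρ·baseline)`. A report drawing no reaction receives the
designated fallback PT ("drug ineffective"), so generated files never
contain quarantinable reaction-less reports; consequently the fallback's
realized frequency exceeds its baseline and marginal-frequency checks
apply to the other terms. Duplicate versions (geometric count at
`duplicate_rate`) modify only mutable fields — report date, primaryid,
possibly one trailing reaction — with strictly increasing
`(FDA_DT, PRIMARYID)` and the final version equal to the truth, so "keep
the latest" is observable and a manifest records the right answer.

Because exposure and events are independent Bernoulli per report, the
2×2 cells are binomial sufficient statistics of the generator;
`simulate_contingency()` samples them directly. The replicated
experiments use this marginalized form — 2,000 null replicates at 20,000
reports (5% exposure, 2% event rate, where cell counts are large enough
for the Woolf interval to be well calibrated), and 500 recovery
replicates per ρ ∈ {2, 5, 10} at 50,000 reports with a rare event
(0.2%), where the odds ratio approximates the injected rate ratio —
while the file-level generator is exercised end-to-end at 50,000 cases
with 30% duplicates in the acceptance script. These problem sizes are the
package's chosen study conditions and are fixed in the test suite.

What the generator does *not* emulate: misspelled free-text drug names,
correlated reaction clusters, reporting-rate drift over calendar time,
multi-outcome reports (off by default, since the reference outcome
denominators imply one outcome per report), and duplicated cases under
*different* CASEIDs — the last being exactly the fuzzy-duplication
problem the CASEID rule cannot see. Passing tests therefore demonstrate
correctness of the machinery under the stated generative model, not
robustness to every pathology of real spontaneous-report data.

## Known limitations

- Disproportionality flags reporting associations, not causality;
  confounding by indication is untouched (ALS itself drives death,
  disease progression and respiratory events in the reference pool).
- The onset proxy conflates reporting delay with true latency.
- The bundled PT→SOC table covers the reference terms only; real MedDRA
  coverage must be supplied by the user.
- The published headline tables (86 PTs, 20 SOCs) are not reproducible
  without the full FAERS extract; the package's contract is the audit
  plus full validation on synthetic ground truth.
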