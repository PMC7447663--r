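---
title: "Disproportionality signal detection with pvsignal: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection with pvsignal: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The case/non-case design

Spontaneous-report databases collect individual case safety reports
(ICSRs): one report per patient, each listing one or more suspected drugs
and one or more coded adverse-event terms, plus demographics, onset time
and final outcome. Whether an event is reported *disproportionally* often
for a drug is assessed by comparing the event's share among reports
mentioning the drug against its share in the rest of the database. For an
exposure definition (one drug, or a therapy class) and an event query, the
de-duplicated report set partitions into the 2x2 table

|              | event | no event |
|--------------|-------|----------|
| exposed      |  A    |   B      |
| not exposed  |  C    |   D      |

with `N = A + B + C + D` and the expected cell count under independence
`N_expected = (A + B)(A + C) / N`. The unit is the report: a report with
two thyroid terms contributes once to a thyroid-group cell, because the
case series counts report cases, not event mentions.

`pvsignal` applies this design to immune checkpoint inhibitor (ICI)
endocrinopathies — the worked domain throughout the package — but every
statistical function operates on plain report sets and catalogs, so other
drug/event domains only need their own catalog.

## The two statistics

**Information component (IC).** The shrinkage observed-to-expected measure
from the Bayesian confidence propagation neural network framework:

\[ IC = \log_2 \frac{A + 0.5}{N_{expected} + 0.5} \]

The additive 0.5 keeps IC defined at `A = 0` and pulls rare-event
estimates toward zero, which is why IC is preferred for *identifying*
signals in very large databases. Its 95% credibility bounds use the
asymptotic expansion

\[ IC_{025} = IC - 3.3\,(A+0.5)^{-1/2} - 2\,(A+0.5)^{-3/2}, \qquad
   IC_{975} = IC + 2.4\,(A+0.5)^{-1/2} - 0.5\,(A+0.5)^{-3/2} \]

with `IC025 > 0` as the signal threshold. The screening literature rarely
prints the interval formula next to its results; we adopted this expansion
as the primary method because it reproduces, to the printed two decimals,
every published interval we use as a check (e.g. a count of 747 with point
IC 6.74 gives a lower bound of 6.62). An exact Gamma-quantile variant —
`log2` of the 2.5% and 97.5% quantiles of Gamma(shape `A + 0.5`, rate
`N_expected + 0.5`) — is available via `ic_method = "gamma"` as an
independent cross-check; the two agree closely once `A` is in the tens.

**Reporting odds ratio (ROR).** `ROR = AD / BC`, with the Woolf interval
`exp(log ROR ± 1.96 sqrt(1/A + 1/B + 1/C + 1/D))`. The ROR is used for
*comparing* reporting between subgroups (e.g. combination therapy versus
monotherapy). With any zero cell the ROR is flagged non-estimable rather
than continuity-corrected, because screening instead applies a
minimum-count rule: ROR significance requires the lower CI bound above 1
**and** `A >= 3` (the `min_count` argument). Algebraically
`ROR > 1  ⇔  AD > BC  ⇔  A > N_expected  ⇔  IC > 0`, so the two statistics
always agree in direction; they differ in shrinkage and calibration.

**Strength categories.** Positive `IC025` values across an endocrine
screen separate, under one-dimensional 3-means clustering
(`cluster_ic025()`, deterministic min/median/max initialization, Lloyd
iterations), into bands whose boundaries motivate the fixed cut points:
`weak` (0–3), `moderate` (3–5), `strong` (5+), with `none` below zero.
`classify_signal()` applies the fixed thresholds; the clustering function
is exposed so the derivation can be re-run on any screen.

No multiplicity correction is applied beyond the `IC025 > 0` criterion;
the screen returns raw counts so users can add corrections if their
setting warrants them.

## Exposure classes and the term catalog

Five ICI drugs are recognised by default: ipilimumab (anti-CTLA-4),
nivolumab and pembrolizumab (anti-PD-1), atezolizumab and durvalumab
(anti-PD-L1). `classify_exposure()` assigns each report exactly one label:
a monotherapy label when exactly one ICI is present, `combination` when an
anti-CTLA-4 drug co-occurs with an anti-PD-1/PD-L1 drug, `other_multi_ici`
for multi-ICI reports without that backbone (e.g. nivolumab plus
pembrolizumab, which published combination listings never include), and
`non_ici` otherwise. Non-ICI co-medication never changes the label; this
is an assumption — spontaneous reports do not say which suspected drug
"owns" the event — and classification is deliberately invariant to it.
Drug names are matched exactly after lower-casing and trimming; fuzzy
matching is out of scope.

Licensed event dictionaries cannot be redistributed, so
`builtin_endocrine_catalog()` ships an open miniature catalog keyed by
exact strings: the endocrine preferred terms used in ICI pharmacovigilance
and the group queries the analysis needs (`ICI-DM`, the four
insulin-deficient diabetes terms; `thyroid_dysfunction`;
`hypophysitis_hypopituitarism`; `adrenal_insufficiency_group`; and
`endocrine_all`, the union). The analysis only requires term-to-group
resolution, which exact strings provide; hierarchy levels and standardized
queries of the licensed dictionary are not modelled. Catalogs serialize to
editable YAML/JSON.

## De-duplication and descriptive conventions

Reporting systems receive the same case more than once. Lacking a
published linkage rule, duplicates are defined as records sharing a
`report_id`; `deduplicate_reports()` keeps the record with the fewest
missing fields (ties: first occurrence), which is deterministic, auditable
and idempotent. Missing values are explicit `unknown` sentinels, never
dropped rows; descriptive percentages use the n/N convention in which only
reports with a known value enter a field's denominator. The
male-to-female ratio is reported to one decimal; a fatal-type outcome is
any of death, life-threatening, hospitalization, or another medically
critical condition, and the fatal/recovered fractions are taken over
reports with any final outcome recorded.

## Time to onset

Onset analyses run on the natural-log scale because onset-time
distributions in this setting are strongly right-skewed and roughly
log-normal. `summarize_onset()` reports the median and quartiles (linear
interpolation between order statistics, the type-7 quantile — stated
because IQR values depend on the convention), the proportions in the bins
(0, 12], (12, 24], (24, 48], (48, ∞) weeks and cumulative proportions at
12/24/48 weeks; bins close on the right so "within 12 weeks" means
`onset <= 12`. Zero-week (same-day) onsets are set to 0.5 weeks — half the
resolution unit — before the log transform, keeping them in the analysis
deterministically. Two groups are compared by a pooled two-sample t test
when a two-sided F test of variance equality at α = 0.05 does not reject,
and by Welch's t test otherwise; the gate is our uniform policy where the
published practice names both tests without a selection rule. Three or
more groups use one-way ANOVA on log weeks. The gate's p value is returned
so the choice is auditable.

## The synthetic report generator

Access-restricted source databases cannot ship with a package, so
`simulate_icsr()` generates databases with the statistical structure the
analysis assumes, making every downstream stage testable end to end:

* **Drugs** are independent Bernoulli draws per report from the menu's
  marginal probabilities, with empty draws rejection-resampled; a
  `combo_probability` arm forces ipilimumab plus a random anti-PD-1/PD-L1
  partner onto the report.
* **Events** are independent Bernoulli per preferred term given the drug
  set — multi-event reports arise naturally — at probability
  `baseline × multiplier` when a signal drug is present (multipliers
  combine by maximum, clipped to 1). A `SignalSpec`-style data frame of
  (drug, event, multiplier) rows is the ground truth that recovery tests
  check against.
* **Onset** is log-normal per (exposure class, event group), defaulting to
  medians between 7 and 17 weeks depending on the pair — early
  anti-CTLA-4 pituitary/adrenal toxicity, early thyroid toxicity, late and
  dispersed insulin-deficient diabetes under anti-PD-1 — with a 12-week
  median default elsewhere.
* **Demographics, missingness, outcomes** follow the descriptive profile
  of ICI endocrinopathy case series: male share 60%, regional mix
  Europe > Americas > Asia, health-professional notifiers ~88%, reporting
  years concentrated in 2017–2019, onset recorded for ~45% of reports,
  final outcome for ~59%, and roughly 70% recovered among those.
* **Duplicates** are injected at `duplicate_rate` by re-emitting a report
  under the same ID with one extra field masked, so de-duplication
  provably recovers the original set.

One master seed governs everything; each stage draws from a substream
derived deterministically from it, and the caller's RNG state is restored
afterwards, so databases are bit-reproducible.

Because rejection resampling conditions each report on having at least one
drug and one event, empirical marginals exceed nominal ones by a factor
`1/(1 - P(empty draw))`; with the default menus this conditioning is at
the percent level and odds-ratio-type targets are essentially unaffected
(conditioning multiplies both odds by the same factor). Configurations
used for marginal-calibration tests include a near-certain filler drug so
the effect is negligible. What the generator does *not* emulate: secular
reporting trends within a year, correlated event co-occurrence beyond
shared drug exposure, free-text drug-name noise, and record-linkage-style
near-duplicates with differing IDs. Passing recovery tests therefore show
the statistics and plumbing are correct under the stated model, not that
real databases satisfy that model.

## Problem sizes and numerical choices

The shipped tests exercise: contingency construction against an
exhaustive per-report loop on random fixtures up to 500 reports; Woolf CI
coverage over 1,000 null tables with 2,000 reports per row (nominal 94–96%
band); planted-signal recovery over 20 replicates of 100,000-report
databases (multiplier 10, baseline 0.001, exposure prevalence 0.05),
requiring the planted pair flagged with `IC025 > 0` and ROR within a
factor 1.5 of 10 in at least 18 of 20; a 50,000-report null screen in
which at least 95% of pairs must stay non-significant; and 1,000-replicate
type-I-error checks (3.6–6.4% acceptance band at α = 0.05) for both onset
test paths. These sizes give stable Monte-Carlo bands while keeping a full
run in minutes on one core.

Numerical details worth stating: IC and its bounds are closed-form, no
iteration; `cluster_ic025()` requires at least three distinct positive
values and errors otherwise (fewer cannot define three bands);
`stats::kmeans` with explicit Lloyd iterations and fixed initial centers
makes the clustering seed-free; ROR with a zero cell is non-estimable by
design, not an exception; an empty onset vector yields `n = 0` with `NA`
summaries rather than an error; and exports round to one decimal
(percentages) or two (IC/ROR) in TSV for human reading while JSON exports
keep full precision.

## Known limitations

Disproportionality quantifies reporting association, not causation or
clinical risk; under-reporting, confounding by indication and stimulated
reporting all distort it. The package deliberately omits other
disproportionality statistics (PRR, EBGM), regression-based confounding
adjustment, record-linkage duplicate detection, and survival-style onset
modelling with censoring. The built-in catalog is a miniature stand-in:
analyses of other event domains need a user catalog, and exact-string
matching presumes coded input.
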