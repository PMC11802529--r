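---
title: "Disproportionality analysis of spontaneous ADR reports: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of spontaneous ADR reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous reporting systems (SRS) such as WHO VigiBase collect individual
case safety reports: a suspected drug, one or more coded adverse reactions,
demographics and regulatory seriousness outcomes. Because an SRS has no
denominator of exposed patients, drug safety surveillance relies on
*disproportionality*: does a reaction appear among a drug's reports more
often than among the reports of comparator drugs? pvsignal implements this
workflow for a five-drug cohort of hepatic anti-fibrotic agents whose
published VigiAccess count tables ship with the package, and generalizes it
to any report-level or aggregate dataset in the same shape.

## Data model and the occurrence convention

Reactions are coded with a two-level terminology: preferred terms (PTs)
nested in 27 System Organ Classes (SOCs). A report's reactions are a *set*
(duplicates collapse), and unparseable demographics map to an explicit
`"unknown"` level rather than `NA`, so strata always partition the reports.

Counting follows one convention everywhere: a report contributes at most 1
to each PT it lists, and its contribution to a SOC is its number of distinct
listed PTs mapping to that SOC. Consequently, per drug,

$$\sum_{\text{SOC}} \text{soc\_count} \;=\; \sum_{\text{PT}} \text{pt\_count},$$

an invariant the validator enforces whenever both sections are present and
the test suite re-derives by brute-force recounts of generated raw reports.
Public aggregate interfaces do not state whether their SOC counts are
report-level or reaction-level; the occurrence convention is this package's
declared choice, made because it keeps the conservation identity exact and
reproduces the packaged tables' per-SOC percentages.

Two totals exist per drug: the report count `n_reports` and the occurrence
total (sum over SOC counts). Demographic strata for sex, age band and
continent must sum to `n_reports`; the reporting-year axis is allowed to
undershoot, because published year tables typically stop at the last full
calendar year.

## The estimators

For target drug $g$ and target term $t$, with cells $a, b, c, d$ as in the
README:

$$\mathrm{ROR} = \frac{ad}{bc}, \qquad
\mathrm{CI}_{95} = \exp\!\left(\ln \mathrm{ROR} \pm 1.96\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right)$$

$$\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}, \qquad
\mathrm{CI}_{95} = \exp\!\left(\ln \mathrm{PRR} \pm 1.96\sqrt{\tfrac1a - \tfrac1{a+b} + \tfrac1c - \tfrac1{c+d}}\right)$$

The PRR variance uses the subtraction form (the delta-method variance of a
log ratio of two binomial proportions); the additive form sometimes seen in
print overstates the variance and does not reproduce published intervals.
Significance rules: an ROR signal needs ROR > 2, CI lower bound > 1 and at
least three cases ($a \ge 3$); a PRR signal needs PRR > 2 and $a \ge 3$.
Pairs with $a < 3$ are screened but marked non-evaluable and never flagged.
No multiple-testing adjustment is applied; flags are raw screening
decisions, as is standard for these frequentist SRS screens.

Numerical choices:

- Cells are coerced to doubles before forming $ad$ — the packaged tables are
  large enough to overflow 32-bit integer products.
- A table with any zero cell receives the Haldane–Anscombe +0.5 on **all
  four** cells, flagged via `correction_applied`; evaluability still refers
  to the uncorrected $a$, so a corrected pair with $a < 3$ can never be
  flagged.
- Displayed percentages are rendered half-up to 2 decimals; every
  comparison in code and tests uses unrounded values.
- Rankings (top-N PTs, forest rows) break count ties lexicographically by
  term name, so output is total-ordered and reproducible.

Exact identities covered by property tests: swapping target and comparator
inverts the ROR and exchanges the CI bounds reciprocally; scaling all four
cells by $k$ fixes both point estimates and narrows CIs monotonically; and
the ROR always lies at least as far from 1 as the PRR on the same side,
with equality only at 1 (since $\mathrm{ROR} = \mathrm{PRR} \cdot
\frac{(c+d)/d}{(a+b)/b}$).

## Occurrence vs report counting units

`build_contingency()` supports two units. In **occurrence** mode (default),
$a + b$ is the drug's total ADR occurrences at the requested level — the
only unit computable from published aggregate tables, and the unit that
reproduces the published gastrointestinal ROR/PRR of this cohort to within
0.2%. In **report** mode, $a + b$ is the drug's report count; at PT level
this works from any aggregate (PT counts are per-report by the set
convention), while at SOC level it needs distinct-report SOC counts, which
`aggregate_reports()` stores (`soc_reports`) but published tables lack —
requesting it there raises an error naming the missing section.

The exact denominators behind the published cohort's headline ROR/PRR are
not recoverable from the printed tables; reconstruction from the 27-SOC
table yields 4.6242 / 3.5637 against the printed 4.629 / 3.566, so the
package declares 1% relative agreement as reproduction, prints that
tolerance in the `reproduce_paper()` report, and meets it with ~0.1% to
spare.

## The synthetic SRS generator

`srs_config()` parameterizes a complete data-generating process:

- **Drug assignment**: categorical with positive weights; defaults
  proportional to the packaged cohort's report totals.
- **Reactions**: each vocabulary PT $t$ enters a report of drug $g$
  independently with probability $p_{gt}$ where
  $\mathrm{odds}(p_{gt}) = \mathrm{odds}(\text{baseline}_t) \times m_{gt}$,
  and $m_{gt}$ is the injectable signal strength (default 1). This
  independence is the simplest structure under which the 2×2 estimators are
  consistent; PT–PT correlation is deliberately out of scope.
- **Demographics**: independent categoricals; defaults are the pooled
  shares of the packaged cohort (57.1% female, 35.3% male, 7.6% unknown;
  age mode 45–64; Americas-dominated regions; years 2014–2024 with
  pre-2019 mass spread uniformly).
- **Outcomes**: independent Bernoulli per regulatory category; defaults
  chosen once so the pooled any-serious rate is ≈2%, the magnitude implied
  by the cohort's printed per-drug serious proportions.

Reports drawing zero reactions are redrawn (up to 100 rounds; stragglers
get one PT forced proportionally to their inclusion probabilities, counted
in the `forced_reports` attribute), because real spontaneous reports always
carry at least one reaction. The random stream is consumed field-by-field
in a fixed order — drugs, the reaction matrix in vocabulary order, redraws,
forced picks, sex, age, region, year, outcomes — making generation fully
deterministic given the configuration; tests pin distributional properties
and within-platform reproducibility, not cross-platform byte streams.

**Redraw bias.** Conditioning on ≥1 reaction inflates a PT's marginal
frequency by up to $1/(1-z)$, where $z$ is the zero-reaction probability.
`true_ror()` deliberately returns the *unconditional* closed form — the
target drug's inclusion odds against the odds of the comparators'
weight-pooled mean inclusion probability — because it equals the injected
multiplier exactly under flat comparators, which is the contract recovery
studies are written against. Under a null configuration the conditioning
cancels exactly (all drugs share $z$); under a signal it contributes a
small bias (≲2% in the validation configurations, which carry a
high-baseline filler PT precisely to keep $z$ small). Recovery assertions
therefore use odds-ratio targets with Monte-Carlo bands, never marginal
frequencies.

`recovery_study()` closes the loop: replicate datasets (seeds
`seed + r - 1`) run through the full pipeline — aggregation, report-unit
PT-level 2×2, both estimators — and report mean estimate, relative bias and
95% CI coverage against the configured truth.

## Validation problem sizes

The shipped suite exercises: exact estimator identities on 1,300
randomized tables across two suites; a 400,000-report simulation against the mixed-comparator
closed form (±3 Monte-Carlo SEs on the log odds ratio plus the documented
redraw allowance); signal recovery at $m = 4$, $n = 50{,}000$ (band
[3.6, 4.4]); mean-bias recovery over 100 replicates of $n = 10{,}000$
(within ±5%); and null CI coverage over 200 replicates of $n = 10{,}000$
(within [0.91, 0.99]). These sizes make the stochastic checks sharp enough
to catch estimator or generator defects while keeping the default test run
in the low minutes.

## What the synthetic validation does and does not show

Passing recovery tests shows the estimators and plumbing are correct for
the generator's model: independent reactions given the drug, no duplicate
reports, no reporting-rate drift over time (no Weber effect), no
drug–drug-interaction signals, and missingness that is independent of
everything else. Real SRS data violate all of these to varying degrees —
disproportionality on real data remains a screening tool whose flags need
clinical review, not an effect estimate. Equally, the packaged-cohort
checks show the pipeline reproduces the published arithmetic, not that the
published signal itself is causal.

## Known limitations

- The terminology is a two-level toy hierarchy, not a licensed MedDRA
  build; no HLT/HLGT levels, no multi-axiality.
- Bayesian disproportionality (IC, EBGM) and the chi-square companion
  criterion for the PRR are not implemented.
- The serious-outcome summary needs report-level data; published aggregate
  tables carry only the printed per-drug percentages, so those are shipped
  as reference numbers, not recomputed.
- Report-unit SOC-level contingencies are unavailable for aggregate-only
  inputs (see above) — the error is immediate and named.
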