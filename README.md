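# pvsignal

Pharmacovigilance signal detection on spontaneous-reporting-system (SRS)
data, built around a published safety analysis of five hepatic anti-fibrotic
agents (empagliflozin, liraglutide, candesartan, obeticholic acid,
resmetirom) in the WHO-VigiAccess database. The package is aimed at drug
safety analysts and biostatisticians who need a tested, reproducible path
from individual case safety reports — or from published aggregate count
tables — to descriptive ADR surfaces and disproportionality statistics.

## What it computes

Reports are coded with a two-level MedDRA-style terminology: each preferred
term (PT, e.g. *Nausea*) maps to one System Organ Class (SOC, e.g.
*Gastrointestinal disorders*). For a target drug and a target term, reports
are cross-classified into the standard 2×2 table

|                | target ADR | other ADRs |
|----------------|-----------:|-----------:|
| target drug    | a          | b          |
| all other drugs| c          | d          |

and two disproportionality measures are computed with log-scale Wald 95%
confidence intervals:

- **Reporting odds ratio**: ROR = ad / bc,
  CI = exp( ln ROR ± 1.96 · √(1/a + 1/b + 1/c + 1/d) ).
  A signal requires ROR > 2, CI lower bound > 1, and a ≥ 3.
- **Proportional reporting ratio**: PRR = [a/(a+b)] / [c/(c+d)],
  CI = exp( ln PRR ± 1.96 · √(1/a − 1/(a+b) + 1/c − 1/(c+d)) ).
  A signal requires PRR > 2 and a ≥ 3.

Tables containing a zero cell get the Haldane–Anscombe +0.5 correction on
all four cells, flagged in the output. Around the estimators sit the
descriptive surfaces of a typical SRS study — SOC report rates (per drug and
pooled), top-N PT rankings, demographic summaries with the female:male
ratio, serious-outcome proportions — plus a synthetic SRS generator with
injectable per-(drug, PT) odds multipliers, so the whole pipeline can be
validated end-to-end by parameter recovery (see the methods vignette,
`vignettes/pvsignal-methods.Rmd`).

## Worked example

The published VigiAccess count tables ship with the package:

```r
library(pvsignal)
fx <- load_paper_fixture()

ct <- build_contingency(fx$counts, "liraglutide", "Gastrointestinal disorders")
ct
#> <contingency_table> liraglutide x Gastrointestinal disorders
#>             target ADR other ADRs
#> target drug      28252      68299
#> other drugs      10191     113926

dplyr::bind_rows(ror(ct), prr(ct))[, c("metric", "estimate", "ci_low", "ci_high", "significant")]
#>   metric estimate ci_low ci_high significant
#> 1    ROR    4.624  4.512   4.739        TRUE
#> 2    PRR    3.564  3.490   3.639        TRUE
```

Liraglutide's reports are 4.6 times as likely to involve a gastrointestinal
reaction as those of the other four agents combined, with a confidence
interval well clear of 1 — a gastrointestinal safety signal under both
criteria (the published analysis prints 4.629 and 3.566 for these
quantities). Screening every (drug, SOC) pair and shaping the
gastrointestinal rows for a forest plot:

```r
sig <- screen_signals(fx$counts, level = "soc", metrics = "ror")
forest_data(sig[sig$term == "Gastrointestinal disorders", ])
#>                                           label estimate ci_low ci_high significant
#> 1      liraglutide | Gastrointestinal disorders   4.6242 4.5121  4.7392        TRUE
#> 2       resmetirom | Gastrointestinal disorders   1.4392 1.0805  1.9172       FALSE
#> 3 obeticholic acid | Gastrointestinal disorders   0.5090 0.4802  0.5394       FALSE
#> 4      candesartan | Gastrointestinal disorders   0.3848 0.3710  0.3991       FALSE
#> 5    empagliflozin | Gastrointestinal disorders   0.2948 0.2859  0.3039       FALSE
```

Only liraglutide is flagged: resmetirom's point estimate exceeds 1 but rests
on 61 cases, and the remaining agents report gastrointestinal reactions
*less* often than the pooled comparators. `reproduce_paper()` recomputes all
published headline numbers (totals, demographic ratios, SOC rates, the
gastrointestinal ROR/PRR) side by side with the printed values,
`run_analysis()` writes the full bundle (summaries, signal table, forest
TSV/PNG) to a directory, and `inst/cli/pvsignal.R` exposes the same
functions as `analyze` / `simulate` / `reproduce-paper` / `recovery-study`
subcommands.

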