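# pvsignal

Disproportionality signal detection for spontaneous adverse-event
reports, in the style of an FDA Adverse Event Reporting System (FAERS)
pharmacovigilance study. The package is aimed at drug-safety analysts
who want a fully scripted, reproducible version of the standard
workflow: ingest the quarterly ASCII tables, deduplicate case versions,
restrict to reports where the drug of interest is the primary suspect
(role code PS), map events to MedDRA Preferred Terms (PT) and System
Organ Classes (SOC), and score every drug–event pair against the
background of all other reports.

## The statistics

For a drug–event pair, counts are laid out in the usual 2×2 table over
unique (report, event-label) pairs — `a` target drug with the event,
`b` target drug with other events, `c` other drugs with the event, `d`
the rest, `N = a+b+c+d` — and four measures are computed:

- **ROR** `= ad/bc`, with Woolf 95% CI
  `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`; zero cells get the
  Haldane–Anscombe +0.5 correction.
- **PRR** `= [a/(a+b)] / [c/(c+d)]` with its log-scale CI, paired with
  the Pearson chi-square `N(ad−bc)² / [(a+b)(c+d)(a+c)(b+d)]`.
- **BCPNN information component** `IC = log2((a+0.5)/(E+0.5))` with
  `E = (a+b)(a+c)/N`; its lower 95% credibility bound `IC025` is the
  log2 of the 2.5% quantile of a Gamma(a+0.5, E+0.5) posterior.
- **MGPS / EBGM**: the relative reporting rate gets a two-component
  gamma mixture prior whose five hyperparameters are fitted by
  maximizing the negative-binomial mixture marginal likelihood
  (`fit_mgps()`); `EBGM` is the posterior geometric mean and `EB05`
  the 5% posterior quantile.

A pair is a **signal** when all enabled rules fire jointly: ROR lower
CI bound > 1; PRR ≥ 2 with chi-square ≥ 4; IC025 > 0; EB05 > 1; and at
least 3 case reports.

Around that core sit stratified (age/sex), concomitant-exclusion,
comparator, demographic and time-to-onset analyses, and a synthetic
FAERS-style generator (`synthetic_config()` / `generate_reports()`)
whose expected contingency cells are available in closed form
(`expected_tables()`), so calibration, power and estimator-bias
properties are testable without any download.

## Worked example

```r
library(pvsignal)

cfg <- synthetic_config(
  n_reports = 20000,
  signals = list(list(drug = "fondaparinux", pt = "haematoma", rho = 8),
                 list(drug = "fondaparinux", pt = "pt_150", rho = 10)))
reports <- deduplicate_reports(generate_reports(cfg, seed = 1))
scan <- signal_scan(reports, "fondaparinux", catalog_vocabulary(cfg))
print(scan, n = 2)
```

```
<signal_scan> drug 'fondaparinux' at PT level: 20000 report(s), 59776 pair(s), 250 event label(s), 2 signal(s)
     event cases                ROR                PRR   chisq          IC        EBGM signal
 haematoma   719  6.44 (5.86, 7.08)  5.59 (5.14, 6.07) 1924.13 2.04 (1.94) 4.13 (3.89)   TRUE
    pt_150    47 7.16 (4.99, 10.28) 7.10 (4.96, 10.16)  155.41 2.22 (1.78) 4.36 (3.69)   TRUE
... 248 more event label(s)
```

The two injected pairs — a haematoma signal with an 8-fold reporting
multiplier and a rare-PT signal at 10-fold — are the only two event
labels that satisfy the joint four-algorithm criterion; `cases` is the
`a` cell, the parenthesized values are the 95% CI bounds (ROR, PRR),
the IC025 credibility bound and the EB05 posterior quantile. The 248
null PTs show ROR ≈ EBGM ≈ 1.

`run_pipeline()` executes the same chain end to end (ingest →
deduplicate → PS filter → contingency → prior fit → scoring → strata /
exclusion / comparator / onset profiles) and writes the score tables,
profiles, quality log and a run manifest as CSV/JSON;
`inst/scripts/pvsignal-pipeline.R` is a thin shell wrapper over it.

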