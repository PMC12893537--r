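---
title: "Disproportionality signal detection: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous reporting systems such as FAERS collect adverse-event
reports without exposure denominators, so incidence cannot be
estimated. What can be estimated is *disproportionality*: whether a
drug–event pair is reported more often than the composition of the rest
of the database predicts. This package implements the four estimators
in routine pharmacovigilance use — frequentist (ROR, PRR with Pearson
chi-square) and Bayesian (BCPNN information component, multi-item
gamma-Poisson shrinker) — on a shared contingency layer, together with
the surrounding ETL, stratification and profiling steps. All findings
such a pipeline produces are reporting associations, not causal or
incidence statements; that caveat carries over from the data source,
not from any implementation choice.

## Counting conventions

**Case, not version.** A FAERS case may be submitted repeatedly;
`deduplicate_reports()` groups report versions by case id and keeps the
most recent report date. The tie-break on equal dates is the larger
`primaryid`, which is monotone with id issuance and makes the operation
deterministic and idempotent. Partial (year- or month-only) dates are
padded with 01 so they still order versions, but are treated as missing
wherever an actual day interval is computed.

**The counting unit is the unique (report, event-label) pair.** A
report contributes at most one count to any PT, and at most one per SOC
after rollup, however often a term repeats. This convention reproduces
both report-level SOC case counts and event-level margins and is the
dominant one in FAERS disproportionality work. `N` is the total number
of pairs in the deduplicated dataset; the background for a target drug
is everything reported for other primary-suspect drugs, unrestricted.
Tables with `a = 0` are not emitted, since the signal criteria require
at least three reports anyway.

**One SOC per PT.** MedDRA is multi-axial, but SOC-level scoring
partitions events, so the vocabulary map enforces a single primary SOC
per PT and refuses conflicting duplicates. PTs missing from the
user-supplied vocabulary accumulate under an explicit `unmapped` bucket
rather than failing the run, and grouping of clinically overlapping PTs
is left to the analyst (it has no canonical definition).

## Statistical conventions

The frequentist forms are the standard ones (Woolf intervals on the log
scale; Pearson chi-square with an optional Yates correction that is off
by default — at the counts where signals are declared the two differ
negligibly). Tables with a zero cell receive the Haldane–Anscombe +0.5
on all four cells and are flagged `corrected` rather than silently
altered.

For the information component the two-parameter gamma convention is
used: `IC = log2((a+0.5)/(E+0.5))` and IC025 from the 2.5% quantile of
Gamma(a+0.5, E+0.5). This convention was chosen over the original
beta-prior formulation because it is self-consistent with the shrinker
(`IC = log2` of the shrunk observed-to-expected ratio, so published
IC/EBGM pairs agree row by row) and its credibility bound reproduces
published IC025 values to the printed precision; the acceptance suite
checks exactly that.

The gamma-Poisson shrinker places a two-component gamma mixture prior
on the relative reporting rate λ of each pair; marginally each observed
count is a mixture of negative binomials, and `fit_mgps()` maximizes
that likelihood over the five hyperparameters with L-BFGS-B under box
constraints (all parameters ≥ 1e-6, mixture weight inside the unit
interval). EBGM is the posterior geometric mean, evaluated through the
digamma function; EB05 is found by bisection on the posterior mixture
CDF to an absolute tolerance of 1e-8 — exact rather than fast, which is
the right trade at desk scale.

**Multimodality of the shrinker likelihood.** On weakly dispersed cell
sets — for example a dataset in which nearly every pair is at its
independence expectation — the gradient path from the conventional
start (0.2, 0.1, 2.0, 4.0, 1/3) collapses both mixture components into
a degenerate spike at λ = 1. That optimum is inferior: a near-null
component plus a small-weight broad component has visibly higher
likelihood, and is the configuration that lets genuinely elevated pairs
escape shrinkage. `fit_mgps()` therefore also starts from
(0.2, 0.1, 2000, 2000, 0.05), which encodes that regime, and keeps
whichever optimum scores the higher likelihood. Sensitivity of this
fit to starting values is a documented property of gamma-Poisson
shrinkage implementations generally; exploring several starts is the
accepted remedy.

## Signal criteria

`signal_thresholds()` defaults to the internationally used joint rule:
ROR lower 95% bound strictly above 1; PRR at least 2 together with
chi-square at least 4; IC025 strictly above 0; EB05 strictly above 1;
and at least `min_cases = 3` reports for the pair. The combined flag is
the conjunction — an event must clear all four algorithms — which
favors specificity over sensitivity; `combine = "any"` is available
when a screening union is wanted. No multiplicity correction is
applied, matching routine practice in this field; the consequence (an
inflated family-wise error over hundreds of PTs) is a known limitation
of the method family, which is why the joint criterion and the
case-count floor exist.

## Stratified, exclusion and comparator analyses

Strata (age `<18 / 18–65 / ≥65 / unknown` at the conventional cut
points, or sex) are self-contained: each stratum's tables are built
against that stratum's own background, so stratum tables add
cell-by-cell to the pooled table — an invariant the suite checks
directly. The concomitant profile counts, among the target drug's
reports with a given PT, reports carrying any non-target drug entry
(any role code) in each antithrombotic class; class rows deliberately
overlap and only the none-row is exclusive. The exclusion analysis
drops every report — target and background alike — containing any
anticoagulant or antiplatelet other than the target itself, then reruns
the identical chain; the comparator analysis reruns it per drug with
one shared prior fit so that scores are comparable across drugs.

Time to onset is the whole-day difference between the event onset date
and the therapy start of the first primary-suspect entry; same-day
onset is 0 days, negative intervals are excluded and counted in the
quality log (the source data does not say how such records should be
treated, so they are surfaced rather than guessed at), and bins use the
conventional 30-day grid with inclusive upper bounds. Outcome
percentages use the total of outcome mentions as denominator — a report
may carry several outcomes — while all report-level fields use the
report count; both conventions are checked against published marginal
percentages in the acceptance suite.

## The synthetic generator

`generate_reports()` draws, per report: a primary-suspect drug from a
configurable market basket; a categorical number of concomitants; a
zero-truncated-Poisson number of event draws from the PT catalog,
re-weighted multiplicatively by any injected signal and uniqued within
the report; demographics from configurable level probabilities with
explicit missing mass; a uniform therapy-start date with an exponential
time to onset; and, at a configurable rate, an earlier-dated duplicate
version of the same case differing only in report date and id. A single
seed governs a fixed stage order of draws, so a configuration and seed
reproduce the dataset byte for byte through the ASCII writer.

Default levels emulate the marginal composition of a large
anticoagulant cohort: 48.7% female, 39.2% aged 65 or older,
72.3% subcutaneous dosing, consumer-dominated reporting, roughly a
third of ages, onsets and regions missing, about three events per
report (λ = 2.87 zero-truncated), an exponential time to onset with a
5-day median (mean 5/ln 2 ≈ 7.21 days), and a 10% duplicate-version
rate.

Two design choices matter for interpretation. First, event draws are
with-replacement-then-unique, because then the probability that PT *p*
appears on a report with *k* draws is exactly `1 − (1 − π̃_p)^k`, which
makes `expected_tables()` a genuinely closed-form oracle for every
contingency cell; the cost is that the expected pair total falls about
1.5% below `n ×` mean draws on the default Zipf-skewed catalog (the
suite asserts both the exact value and that bound). Second, signal
injection multiplies the selection probability of one PT for one drug
and renormalizes; for rare PTs the induced reporting odds ratio is
essentially the multiplier, while for common PTs renormalization
saturates it well below (an 8-fold multiplier on the most common toy PT
induces ROR ≈ 6). Power and recovery checks therefore inject on rare
PTs and always compare estimates against the analytically induced
ratio, not the raw multiplier.

What the generator does **not** emulate: reporting waves over calendar
time, country effects, correlated event co-occurrence beyond shared
drug weights, real drug-name noise beyond alias lookup, or
between-pair heterogeneity under the null. Passing the calibration and
power suites therefore shows the estimators behave correctly under the
stated generative model — it does not certify behavior on real
spontaneous-report data, where duplicates are fuzzier and confounding
is real.

## Numerical choices and degenerate inputs

- Gamma and negative-binomial computations use the standard library
  quantile/density routines; independent test oracles use hand-coded
  densities with `integrate()`/`uniroot()` so implementation and check
  never share a code path.
- EB05 bisection: absolute tolerance 1e-8, bracketed by the component
  quantiles (the mixture quantile must lie between them).
- Malformed ASCII lines (arity mismatch), implausible ages (negative or
  above 130 years), partial dates, reports without events and negative
  onset intervals are never silently dropped: each is counted in the
  quality log attached to the report set and exported by the pipeline.
- Unrecognized role codes default to concomitant; unrecognized sex,
  route, reporter and outcome codes collapse to the catch-all levels
  rather than erroring, mirroring how published report-characteristic
  tables carry other/unknown rows.
- A target drug absent from the dataset yields a warning and an empty
  result, not an error, so batch comparator runs survive sparse drugs.

## Problem sizes

The test suite exercises the full chain at the sizes a desk validation
needs: 50,000-report datasets with 250 PTs for null calibration (at
most 1% of eligible pairs may satisfy the joint criterion) and power
(an injected 10-fold signal must fire on all four algorithms with its
ROR interval covering 10); 10,000 simulated cells for hyperparameter
recovery (fitted marginal likelihood within 0.5% of the generating
parameters'); and 12 replicate datasets at each of 5,000 / 20,000 /
80,000 reports to demonstrate that the ROR log-error against the
closed-form induced ratio shrinks as the dataset grows.
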