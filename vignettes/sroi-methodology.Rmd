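---
title: "Valuation methodology: how sroikit computes a Social Return on Investment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuation methodology: how sroikit computes a Social Return on Investment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sroikit)
```

## The model

Social Return on Investment (SROI) expresses the social value created by a
program as dollars of benefit per dollar invested. `sroikit` implements the
standard five-step SROI accounting pipeline for health programs whose
benefits are avoided cases of preventable conditions: scope the beneficiary
cohort, map outcomes, value each outcome with a financial proxy, adjust for
impact, and compute the ratio with a sensitivity analysis.

Each outcome line is valued per annual cohort as

$$
V = N \times p \times \rho \times c \times
(1-w)(1-d)(1-a)
$$

where $N$ is the cohort size (e.g. mother–infant dyads per year), $p$ the
prevalence or incidence of the condition in the reference population, $\rho$
the relative risk reduction attributable to the program (sourced from odds
ratios in the epidemiological literature), $c$ the financial proxy in AUD
per case (or per person-year for earnings proxies), and $w, d, a$ the
deadweight, displacement and attribution fractions. The product
$(1-w)(1-d)(1-a)$ is the *retention factor*: the share of the gross outcome
the program may legitimately claim. With the case-study adjustments of 5%,
20% and 25% the retention factor is $0.95 \times 0.80 \times 0.75 = 0.57$.

Benefits persisting beyond the first year form a stream
$V_t = V\,(1-\delta)^{t-1}$ for $t = 1..D$, where $\delta$ is the annual
drop-off fraction and $D$ the outcome's duration in years. Streams are
discounted end-of-period at rate $r$:

$$
\mathrm{NPV} = \sum_{t=1}^{D} \frac{V_t}{(1+r)^t}.
$$

The SROI ratio is $(B - I)/I$ for benefit basis $B$ and annual investment
$I$; the *reported* ratio truncates the raw ratio toward zero, matching the
"AU\$ $N$:1" headline convention. The payback period is
$12\,I/B_{\text{annual}}$ months under uniform within-year accrual.

### Two ratio modes

`sroi_evaluate()` offers two bases:

* **simple** — the annual benefit total. This is the mode that reproduces
  the published case-study figures, whose headline ratio is formed from the
  annual totals rather than from discounted streams.
* **npv** — the sum over outcomes of the NPV of each outcome's
  drop-off-decayed stream over its own duration. This is the economically
  conventional basis when benefits persist for many years.

A scenario may carry a `total_benefit_override`, used as the simple-mode
basis in place of the computed outcome sum. It exists because published
analyses sometimes print a headline total that their own rows do not sum
to; the override lets the headline be reproduced while the computed sum
stays visible next to it. The override is an annual-total concept and is
ignored in `npv` mode and in the Monte Carlo analysis, where a fixed total
cannot remain coherent under joint random perturbation.

## The built-in case study

`calvary_fixture()` encodes the SROI analysis of maintaining Baby-Friendly
Hospital Initiative accreditation at a Canberra public maternity unit:
1000 dyads/year, 14 outcome lines (9 infant: diarrhea, respiratory
infection, acute otitis media, necrotizing enterocolitis, higher IQ,
obesity, type 1 and 2 diabetes, SIDS; 5 mother: breast cancer,
cardiovascular disease, formula cost saving, ovarian cancer, hypertension),
investment AUD 24,433.80/year, 4% discount rate, adjustments
(5%, 20%, 25%, drop-off 20%). Durations follow the published groupings:
3 years for the infant infections, 30 years for the lifetime outcomes,
15 years for maternal chronic disease, 2 years for formula savings.

```{r}
res <- sroi_evaluate(calvary_fixture())
glance(res)
```

Seven of the fourteen published row values (diarrhea, respiratory
infection, otitis media, higher IQ, type 1 diabetes, SIDS, hypertension)
reproduce exactly — to the nearest AUD — under the valuation formula above;
the other seven do not reconcile with their own published inputs, and no
intermediate arithmetic is available to explain them. The package carries
those rows' published values as a `printed_value` annotation and surfaces
the disagreement rather than hiding it:

```{r}
fixture_discrepancies(calvary_fixture())
```

Similarly, the published total benefit (AUD 1,375,050) differs from the sum
of the published rows (AUD 1,398,140) and from the engine's computed sum;
the fixture stores the published total as `total_benefit_override`, so
headline reproduction uses the published basis while `total_annual_benefit()`
reports the computed sum. Fixture runs through `run_command()` emit WARN
log lines restating both discrepancies on every run.

Two further published figures are not reproducible from the published
inputs under any convention we tried and are deliberately not matched: the
payback period of 0.63 months (direct computation gives
$12 \times 24{,}433.80 / 1{,}375{,}050 = 0.213$) and the drop-off/discount
sensitivity rows, whose stream arithmetic is unstated.

## Design choices

Where the source analysis left the procedure open, the package fixes one
convention and applies it uniformly:

* **Valuation formula.** The per-row formula is never written out in the
  source; the declared form above is validated by exact agreement with the
  seven reconcilable rows.
* **Breastfeeding rate.** The cohort's 97% breastfeeding initiation rate is
  stored as metadata but *not* multiplied into valuations by default:
  reverse-engineering the reconcilable rows shows they use the full cohort
  of 1000 (e.g. SIDS: $1000 \times 0.03 \times 0.40 \times 89{,}487 \times
  0.57 = 612{,}091$). Setting `apply_breastfeeding_rate = TRUE` exposes the
  alternative.
* **Drop-off** is geometric decay from year 2 onward; year 1 always pays
  the full annual value.
* **Discounting** is end-of-period; the source states the 4% rate but not
  the timing convention.
* **Rounding.** Per-outcome values report to the nearest AUD (consistent
  with every reconcilable row, e.g. 117.79 → 118 and 8.57 → 9); reported
  ratios truncate toward zero, the only convention consistent with the
  reproducible published sensitivity ratios (round-to-nearest would miss
  three of them).
* **Breast cancer risk reduction** appears as 4% in the evidence table and
  4.3% in the sensitivity table's base case; the fixture uses the evidence
  table's 0.04, since that is the stated model input.
* **Type 2 diabetes** has no printed financial proxy; the fixture uses the
  same diabetes treatment cost (AUD 3,131) as type 1.
* **Formula cost saving** has no printed incidence/odds-ratio pair; the
  fixture encodes the 97% initiation rate as incidence and the 15.4%
  national exclusive-breastfeeding rate as the risk-reduction slot.

## Sensitivity analysis

`one_way_table()` is strictly one-at-a-time: each perturbation is applied
to the base scenario alone and rows never compound, matching the
row-per-change layout of deterministic sensitivity tables. When an override
is present it is rescaled exactly so printed-total-based analyses remain
coherent: by $(1-\text{new})/(1-\text{old})$ for a retention adjustment, by
$k$ for a global value multiplier $k$ or a population change, and by an
additive shift of the affected row's reference value times
$(\text{new}/\text{old} - 1)$ for a single outcome's incidence, risk
reduction or unit value (all of which enter the valuation linearly). For a
retention adjustment this yields the closed-form identity

$$
\text{ratio}_{\text{new}} =
\frac{\frac{1-\text{new}}{1-\text{old}}\,B - I}{I},
$$

under which the reproducible published new-case ratios (attribution 50% →
36, deadweight 50% → 28, displacement 0% → 69, value halved → 27, value
doubled → 111) all reproduce exactly with truncation. Drop-off and
discount-rate perturbations have no effect on an annual total, so those
rows are evaluated in `npv` mode against an `npv`-mode base. Two published
SIDS rows and the upper breast-cancer row are each one unit off every
rounding convention we tried; they are reported as computed, not matched.

`monte_carlo_psa()` extends the deterministic analysis: every listed
parameter is drawn independently (uniform or degenerate point
distributions, bounds checked against the parameter's valid range), one
joint draw per iteration, with the raw ratio summarised by mean, SD,
quantiles and the fraction of draws above 1. A single integer seed makes
the analysis exactly reproducible. Because the ratio is linear in each unit
value, symmetric unit-value noise leaves the mean ratio at the
deterministic value, which the test suite exploits as an analytic check.

## The synthetic scenario generator

`generate_scenario()` exists so that every engine and sensitivity operation
is testable without external data. Its defaults emulate the structure of
the case study: 14 outcome lines; incidences from $10^{-4}$ to 1 (the
published table spans 0.008% to 100%); risk reductions 0.01–0.6; financial
proxies sampled *log-uniformly* over 20–90,000 AUD, because the published
proxies span four orders of magnitude (AUD 20.27 to 89,487); durations
drawn from {2, 3, 15, 30} years; adjustments uniform on [0, 0.3]/[0,
0.4]/[0, 0.5]/[0, 0.5]; cohorts of 200–5000; discount rates 0–8%; and
investment drawn as 0.5–20% of the computed total annual benefit, so the
ratio is always defined and usually well above 1, as in the case study.
One integer seed drives a single deterministic stream (suites use
consecutive seeds), and the generator restores the caller's RNG state.

Generated scenarios are structurally valid by construction, but they do not
emulate epidemiological realism: incidence and risk reduction are sampled
independently (no joint distribution), outcome names are synthetic, and no
correlation between proxy size and duration is imposed. Passing property
tests on generated scenarios therefore demonstrates the engine's
mathematical invariants (validation, linearity, monotonicity, NPV
equivalence, round-tripping) — not the epidemiological plausibility of any
particular scenario.

## Numerical conventions and degenerate inputs

* Valuation is pure vector arithmetic in double precision; NPV is an
  explicit year-by-year sum whose agreement with the geometric closed form
  is asserted to 1e-9 relative tolerance in the tests.
* Scenario files round-trip exactly: doubles are written with 17
  significant digits (YAML/CSV) or `jsonlite` 17-digit output (JSON), which
  is lossless for IEEE 754 doubles.
* Fractions may be written as decimals or percent strings (`"26%"`,
  `"0.008%"`); both parse to identical values, and out-of-range or
  unparseable values are validation/parse errors, never silently clamped.
* Zero incidence or risk reduction values a row at exactly 0; duration
  below 1 year, non-positive investment, and adjustments of 1 or more are
  rejected. An empty perturbation list yields an empty table; ties in
  tornado ranking keep input order.

## Problem sizes

Everything here is desk-scale: the case study has 14 rows, property suites
run on 100 generated scenarios, and the Monte Carlo checks use a few
thousand draws — the full test suite and the reproduction script each run
in well under a minute on one CPU.

## Limitations

The engine values outcomes by prevalence × risk-reduction × proxy; it does
not model utilities (no QALY/ICER machinery), currency conversion, age
structure, or uncertainty in the evidence base beyond the distributions the
user supplies. The seven non-reconcilable fixture rows are carried, not
explained; any conclusions drawn from the fixture's headline figures
inherit the source analysis's internal inconsistencies, which this package
makes visible rather than resolves.
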