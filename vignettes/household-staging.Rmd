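---
title: "Staging household readiness to change dietary behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging household readiness to change dietary behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhstage)
```

## The problem and the model

Stage-based behaviour-change interventions need a *staging* step: before an
intervention can be matched to a person's readiness, that readiness has to
be classified. The transtheoretical model (TTM) does this for individuals;
`hhstage` implements a staging instrument for *households*, the unit at
which food is purchased and prepared in many settings. One respondent (in
the original deployment, the female head of household) answers on behalf of
the household, and the algorithm assigns a household-level stage.

The five TTM stages are collapsed to three ordinal levels:

* **P** — pre-contemplation: no intention to change;
* **I** — intention: contemplation and preparation merged;
* **A** — action: action and maintenance merged.

Stages are assigned separately for two dietary component groups — fruits
and vegetables (FV, the "increase" behaviours) and salt, sugar and oil
(SSO, the "limit" behaviours) — and then combined into one overall
household stage.

Two household-specific constructs distinguish this instrument from
individual staging algorithms: **household efficacy** (the respondent's
confidence, on a 5-point scale, that the household can make the change) and
**perceived household cooperation** (expected cooperation from the other
members, also 5-point). Both act as disqualifiers: a household that claims
willingness but reports low efficacy or low expected cooperation is staged
as pre-contemplation, not intention.

## The three-step algorithm (final version)

For each component the final algorithm evaluates, in order:

1. **Self-evaluation (action check).** FV: does the household consume both
   fruit and vegetables daily? SSO: is 30-day consumption of salt, sugar
   *and* oil at or below the recommended limits for the household's size?
   If yes, the component stage is **A** and the staging questions are not
   consulted.
2. **Disqualifiers (pre-contemplation check).** The component stage is
   **P** if any of: not willing to make changes; willing but unsure when;
   confidence 1–4; expected cooperation 1–3.
3. **Residual (intention).** Otherwise — willing to change immediately with
   confidence 5 and cooperation 4–5 — the stage is **I**.

The overall stage is the *lower* (rank minimum) of the FV and SSO stages:
a household is in overall action only when both components are.

Each `stage_household()` result carries a rule trace (`fv_rule`,
`sso_rule`, `overall_rule`) naming the single clause that fired, so any
stage can be audited back to the responses. Because step 2 is a disjunction,
the order in which the four disqualifiers are tested affects only which
clause the trace names, never the stage; they are tested in the order
willingness, timeframe, confidence, cooperation.

Of the 2 × 2 × 5 × 5 = 100 combinations of staging answers, exactly 2 map
to intention when consumption is inadequate and 98 to pre-contemplation —
`enumerate_response_space()` reproduces this split, and the test suite
checks it against an independent brute-force re-statement of the rules.
The intention stage is deliberately narrow: the instrument treats any
hedge (timing, efficacy, cooperation) as pre-contemplation, because
pre-contemplators are the group an intervention most needs to find.

## Earlier algorithm versions

Two earlier versions are implemented for comparative study:

* **Version 2** uses the same staging rules but assesses FV adequacy from
  24-hour serving counts against the daily recommendation of five servings,
  split as 2 fruit + 3 vegetable (`assess_fv_servings()`). Versions 2 and 3
  agree whenever the serving-based and daily-indicator adequacy agree.
* **Version 1** used awareness items (interest in the dietary
  recommendations; already following them) plus willingness and a
  `30_days`/`unsure` timeframe. Its published rules conflict for every
  input (e.g. interest *yes* implies I while willingness *yes* implies A),
  which is why it proved non-functional in practice. `stage_component_v1()`
  applies a documented precedence (following → A; interest no → P;
  willingness no → P; timeframe 30 days → A; willingness yes → A) and
  flags every conflicting input with a `+conflict` suffix in the trace;
  the Version 1 overall combination is the rank *maximum*, with the
  ambiguous (I, A) pair resolved A-dominant and flagged `+ambiguous`.
  Version 1 is included for completeness, not production use.

The timeframe vocabulary is version-specific (`30_days`/`unsure` for
Version 1, `immediate`/`unsure` thereafter): in formative work, households
universally endorsed a 30-day horizon, and only the sharper
immediate/unsure contrast separated intenders from pre-contemplators.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fv_daily_rule` | `both` | — | Fruit and vegetables are collected as separate items; requiring both daily is the conservative reading of "consuming FV daily". `either` is available for sensitivity analyses. |
| `sso_rule` | `all` | — | "Within limits" must hold for salt, sugar and oil jointly; `any` available for sensitivity analyses. |
| `fruit_target`, `veg_target` | 2, 3 | servings/day | The five-serving recommendation split used by the serving-based (Version 1–2) adequacy path. |
| limits chart | per-capita 5 g salt, 30 g sugar, 30 ml oil daily × 30 days × household size | g, g, ml per 30 days | A *placeholder* chart: the locally calibrated chart used in the original deployment is unpublished, so the shipped default is a transparent per-capita construction (sizes 1–10, per-capita linear extrapolation beyond). Any deployment should supply its own chart via `read_config()`. |
| `missing` | `strict` | — | Field data entered by lay volunteers: strict mode fails fast naming household and field; lenient mode leaves the household unstaged and reports the exclusion count. |

Numerical conventions, chosen once and documented so they are auditable:

* consumption exactly **at** a limit counts as within limits (`<=`);
* limits for household sizes beyond the chart are extrapolated per-capita
  from the largest entry and rounded to 1 g (or ml);
* enumerated fields are canonicalised for case and whitespace
  (`YES`/`yes`, `Immediate`/`immediate`, full stage names).

## Item coding for reliability

The final instrument has 17 distinct items: 2 FV + 3 SSO consumption
estimation items, 4 + 4 staging items, household size, and 3 computed
stage items. For internal consistency they are grouped as 8 FV items, 9
SSO items and 15 overall items (FV + SSO, excluding the two per-component
stage items; household size is shared). `instrument_items()` enumerates
the schema and `encode_items()` builds the numeric matrices.

No published coding scheme exists for these items, so the package defines
one and treats it as configuration: binary items 0/1, timeframe
immediate = 1 / unsure = 0, confidence and cooperation on their raw 1–5
scale, SSO quantities as within-limit indicators (0/1), FV consumption as
daily indicators (0/1), stage codes 0/1/2, household size as its integer
value. Indicator coding keeps heterogeneous items on comparable scales so
Cronbach's alpha is well defined; alpha is invariant to the per-item
location shifts this discards.

## Validation statistics

* **Percent agreement** — diagonal share of the 3 × 3 tool × comparator
  confusion table.
* **Quadratic weighted kappa** — chance-corrected agreement with
  disagreement weights $w_{ij} = (i-j)^2/(k-1)^2$:
  $\kappa_w = 1 - \frac{\sum_{ij} w_{ij} O_{ij} / n}{\sum_{ij} w_{ij} p_i q_j}$.
  The quadratic form penalises two-rank disagreements (P vs A) four times
  as heavily as adjacent ones, appropriate for an ordinal stage variable.
  The conventional good-agreement threshold for this design is 0.7.
  Degenerate tables follow an explicit convention: perfect agreement
  returns exactly 1 even though the ratio is 0/0 there; any other
  zero-expected-disagreement input raises an error rather than returning a
  meaningless value.
* **Confidence interval** — a seeded percentile bootstrap over households
  (default 2000 resamples). A bootstrap was preferred over the asymptotic
  (Fleiss–Cohen–Everitt) standard error because validation sessions for
  instruments of this kind are small (tens of households), where the
  normal approximation is doubtful; the asymptotic SE is still reported as
  a secondary output (`weighted_kappa_se()`), and with 0/1 weights the
  statistic reduces to unweighted Cohen's kappa (cross-checked in the
  tests). Resamples with a degenerate marginal are skipped and counted.
* **Cronbach's alpha** — $\alpha = \frac{k}{k-1}\bigl(1 - \sum s_i^2 /
  s_X^2\bigr)$ with $n-1$ variance denominators throughout (the value is
  invariant to the denominator choice if consistent; fixing it makes runs
  bit-reproducible). Zero-variance items are rejected by name.

## What the simulator emulates — and what it does not

`simulate_households()` draws a true stage per component from a
configurable mix (default $\pi = (0.3, 0.4, 0.3)$, a mix in which all
three stages are well represented; the original validation sessions did
not report their observed mix, so this default is a documented choice, not
a calibration) and constructs questionnaire responses that the final
engine maps back to that truth *exactly* — action households get adequate
consumption, intention households the unique intention response profile,
pre-contemplation households one of the three disqualifying patterns
(equal probabilities by default). Serving counts are generated consistent
with the daily indicators so Version 2 stages the records identically.
The comparator — standing in for the motivational-interviewing rater used
to assess concurrent validity — is a noisy ordinal channel: with
probability $d$ (default 0.10) it moves the true stage exactly one rank
(I splits its errors evenly between P and A). Two-rank errors are excluded
as implausible for a trained rater; adding them would need a second
parameter.

This design makes the engine–generator consistency contract exact
(`engine(record) == truth` for every record and seed) and gives closed
forms to test against: the overall-stage marginal under independent
components is $P(\mathrm{overall}=A)=\pi_A^2$,
$P(\mathrm{overall}=P)=1-(1-\pi_P)^2$; and for any overall marginal $p$
the expected weighted kappa is available in closed form
(`expected_weighted_kappa()`) because every comparator error contributes
disagreement weight 1/4, making the observed weighted disagreement $d/4$
regardless of the marginal. For the marginal $(0.3, 0.4, 0.3)$ at
$d = 0.10$ this gives exactly $54/59 \approx 0.915$.

What the simulator does **not** emulate: correlated measurement error
between tool and comparator (the two ratings in a real session are minutes
apart and share context), systematic rater bias, response styles
(acquiescence, central tendency on the 5-point items), item-level
missingness patterns, and any real joint distribution of consumption with
household size. Passing tests therefore demonstrate that the algorithms
and statistics are implemented correctly, not that the instrument is valid
on real households — the latter needs field data.

Seeding: one root seed with per-purpose substreams (sizes, stage draws,
response patterns, consumption noise, comparator), so adding draws for one
purpose never perturbs the others and identical parameters give
byte-identical tables.

## Problem sizes

The test suite enumerates the full discrete response spaces (100 and 16
cells), simulates 300–10 000 households for the recovery and coverage
checks, and uses n = 2000 with k = 8 or 15 items for the Spearman–Brown
alpha checks (tolerance 0.02–0.03, set from the binomial/normal error of
the closed forms at those sizes, before the checks were run). The
reproduction script simulates 10 000 households, where the weighted kappa
estimate is stable to about ±0.005 across seeds.

## Known limitations

* The shipped limits chart is a placeholder; conclusions about SSO
  adequacy with the defaults reflect the per-capita construction, not the
  locally recommended chart the original instrument used.
* The exact identity of the two FV estimation items is reconstructed as
  the fruit-daily and vegetable-daily indicators, and household size is
  assigned to both reliability groups — the only grouping that reconciles
  17 items with the 8/9/15 split.
* Inter-rater and test–retest reliability are out of scope (a single
  scorer computed stages in the original use; repeatability was left to
  future work).
* Version 1 is a faithful reconstruction of a non-functional algorithm;
  its outputs should only be used to study *why* it fails (every trace is
  conflict-flagged).
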