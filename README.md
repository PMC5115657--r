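# hhstage — household stages-of-change staging instrument

`hhstage` is a scoring engine and validation toolkit for a *household-level*
stages-of-change staging instrument targeting five dietary components:
fruits and vegetables (FV — the behaviours to increase) and salt, sugar and
oil (SSO — the behaviours to limit). Stage-matched dietary interventions
need to classify readiness before they can act on it; existing staging
tools classify individuals, whereas food purchasing and preparation are
household decisions. This package implements the household instrument —
questionnaire data model, versioned staging algorithms with auditable rule
traces, consumption-adequacy rules — together with the psychometric
statistics used to validate such instruments, and a seeded simulator that
makes everything testable without real survey data.

It is intended for epidemiologists and intervention researchers who need to
stage households from questionnaire CSVs, and for methodologists studying
household-level staging algorithms.

## The core algorithm

Each household is assigned one of three ordinal stages per component and
overall: pre-contemplation (**P**) < intention (**I**) < action (**A**).
The final algorithm runs three steps:

1. **FV stage** — **A** if the household consumes both fruit and vegetables
   daily; otherwise **P** if any disqualifier holds (not willing to change;
   willing but unsure when; confidence ≤ 4; expected cooperation ≤ 3),
   else **I**.
2. **SSO stage** — same staging rules, with the action check being 30-day
   salt, sugar *and* oil consumption at or below the recommended limits
   for the household's size.
3. **Overall stage** — the lower (rank minimum) of the two:
   `overall = min(FV, SSO)`.

Concurrent validity against a reference rater is measured with percent
agreement and the quadratic weighted kappa

```
kappa_w = 1 - (sum_ij w_ij O_ij / n) / (sum_ij w_ij p_i q_j),
w_ij = (i - j)^2 / (k - 1)^2,
```

with a seeded percentile-bootstrap confidence interval; internal
consistency with Cronbach's alpha, `alpha = k/(k-1) (1 - sum(s_i^2)/s_X^2)`,
on the instrument's 8-item FV, 9-item SSO and 15-item overall groups.

## Worked example

Simulate a validation exercise with known truth, stage the households,
and compute the validity and reliability statistics:

```r
library(hhstage)

sim <- run_simulate(500, seed = 42, misclass = 0.10,
                    out_responses = "responses.csv",
                    out_ratings = "ratings.csv")
st  <- run_stage("responses.csv", output = "stages.csv")
#> staged 500 household(s) with algorithm version 3 (0 excluded)
#> overall stages: P=263, I=187, A=50
#> fired component rules: I:ready=396, A:consumption=301, P:timeframe=120,
#>   P:willingness=100, P:cooperation=42, P:confidence=41

rep <- run_validate("ratings.csv", n_boot = 2000, seed = 17)
#> n=500  agreement=90.8%  weighted kappa=0.898  95% CI [0.868, 0.926]

al <- run_alpha("responses.csv", st)
#> alpha[FV] = 0.186  (8 items, 500 households)
#> alpha[SSO] = 0.148  (9 items, 500 households)
#> alpha[OVERALL] = 0.193  (15 items, 500 households)
```

Reading the output: the stage counts show the simulated mix after the
rank-minimum combination (P dominates because either component can drag
the overall stage down). The rule counts audit *why* components were
staged — e.g. 120 component stages were pre-contemplation because the
household was unsure about timing. Agreement of 90.8% and weighted kappa
0.898 recover the simulated 10% one-rank comparator error (the
closed-form expectation for this design is ≈ 0.884, inside the bootstrap
interval); kappa ≥ 0.7 is the conventional good-agreement bound for this
design. The low alphas are expected here: the simulator draws staging
items independently within a stage, so items share little variance —
alpha reflects the data-generating process, and on this synthetic design
it is a floor, not an estimate of the real instrument's reliability.

Each staged row carries its trace:

```
  household_id version fv_stage sso_stage overall_stage       fv_rule      sso_rule  overall_rule
1      HH00001       3        I         I             I       I:ready       I:ready overall:min=I
2      HH00002       3        A         A             A A:consumption A:consumption overall:min=A
3      HH00003       3        P         I             P P:cooperation       I:ready overall:min=P
```

A thin command-line wrapper with subcommands `stage`, `validate`, `alpha`
and `simulate` is installed at
`system.file("cli", "hhstage", package = "hhstage")`; limits charts and
scoring policies are supplied as YAML/JSON config files (example in
`inst/extdata/config_default.yaml`).

See the vignette (`vignettes/household-staging.Rmd`) for the model,
parameter meanings, numerical conventions and the simulator's scope.

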