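Package: hhstage
Title: Household Stages-of-Change Staging Instrument for Dietary Behaviour
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scoring engine for a household-level stages-of-change staging
    instrument targeting five dietary components (fruits, vegetables, salt,
    sugar and oil). Implements the questionnaire data model (17-item final
    schema), the three versioned staging algorithms with rule traces, the
    consumption-adequacy rules (daily fruit-and-vegetable indicators, the
    two-fruit/three-vegetable serving rule, and a household-size-indexed
    30-day salt/sugar/oil limits chart), and the psychometric validation
    statistics used to evaluate such instruments: percent agreement,
    quadratic weighted kappa with a seeded bootstrap confidence interval,
    and Cronbach's alpha on the 8-item FV, 9-item SSO and 15-item overall
    groups. A seeded household simulator generates questionnaire responses
    with known true stages and a noisy ordinal comparator so every statistic
    is testable end-to-end without real survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
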