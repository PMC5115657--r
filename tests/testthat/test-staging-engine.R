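test_that("final-version component rules match the published mapping", {
  # adequate consumption short-circuits to action
  expect_identical(stage_component_v3(TRUE, "no", "unsure", 1, 1)$stage, "A")
  expect_identical(stage_component_v3(TRUE, "yes", "immediate", 5, 5),
                   list(stage = "A", rule = "A:consumption"))
  # each disqualifier maps to pre-contemplation
  expect_identical(stage_component_v3(FALSE, "no", "immediate", 5, 5),
                   list(stage = "P", rule = "P:willingness"))
  expect_identical(stage_component_v3(FALSE, "yes", "unsure", 5, 5),
                   list(stage = "P", rule = "P:timeframe"))
  expect_identical(stage_component_v3(FALSE, "yes", "immediate", 4, 5),
                   list(stage = "P", rule = "P:confidence"))
  expect_identical(stage_component_v3(FALSE, "yes", "immediate", 5, 3),
                   list(stage = "P", rule = "P:cooperation"))
  # the single intention profile: immediate, confidence 5, cooperation 4-5
  expect_identical(stage_component_v3(FALSE, "yes", "immediate", 5, 4),
                   list(stage = "I", rule = "I:ready"))
  expect_identical(stage_component_v3(FALSE, "yes", "immediate", 5, 5)$stage,
                   "I")
  expect_error(stage_component_v3(FALSE, NA, "immediate", 5, 5),
               "incomplete")
  expect_error(stage_component_v3(FALSE, "yes", "soon", 5, 5), "timeframe")
})

test_that("the 100-cell response space splits 98 P / 2 I against a brute-force oracle", {
  grid <- expand.grid(willing = c(TRUE, FALSE),
                      timeframe = c("immediate", "unsure"),
                      confidence = 1:5, cooperation = 1:5,
                      stringsAsFactors = FALSE)
  expect_identical(nrow(grid), 100L)
  for (ok in c(FALSE, TRUE)) {
    oracle <- vapply(seq_len(nrow(grid)), function(i) {
      oracle_stage_v3(ok, grid$willing[i], grid$timeframe[i],
                      grid$confidence[i], grid$cooperation[i])
    }, character(1))
    engine <- vapply(seq_len(nrow(grid)), function(i) {
      stage_component_v3(ok, grid$willing[i], grid$timeframe[i],
                         grid$confidence[i], grid$cooperation[i])$stage
    }, character(1))
    expect_identical(engine, oracle)
    counts <- enumerate_response_space(3, consumption_ok = ok)
    expect_identical(sum(counts), attr(counts, "space_size"))
    expect_identical(unname(counts[STAGES]),
                     unname(vapply(STAGES, function(s) sum(oracle == s),
                                   integer(1))))
  }
  expect_identical(unclass(enumerate_response_space(3, FALSE))[STAGES],
                   c(P = 98L, I = 2L, A = 0L))
  expect_identical(unclass(enumerate_response_space(3, TRUE))[STAGES],
                   c(P = 0L, I = 0L, A = 100L))
})

test_that("version 2 applies the serving rule then the shared staging rules", {
  # servings (2, 3) are adequate -> action
  expect_identical(
    stage_component_v2(assess_fv_servings(2, 3), "no", "unsure", 1, 1)$stage,
    "A")
  # servings (1, 3) inadequate; intention-qualifying answers -> intention
  expect_identical(
    stage_component_v2(assess_fv_servings(1, 3), "yes", "immediate", 5, 5),
    list(stage = "I", rule = "I:ready"))
  # identical staging rules: v2 and v3 agree whenever adequacy agrees
  grid <- expand.grid(ok = c(TRUE, FALSE), willing = c(TRUE, FALSE),
                      timeframe = c("immediate", "unsure"),
                      confidence = c(1, 4, 5), cooperation = c(1, 3, 4, 5))
  for (i in seq_len(nrow(grid))) {
    expect_identical(
      stage_component_v2(grid$ok[i], grid$willing[i], grid$timeframe[i],
                         grid$confidence[i], grid$cooperation[i]),
      stage_component_v3(grid$ok[i], grid$willing[i], grid$timeframe[i],
                         grid$confidence[i], grid$cooperation[i]))
  }
})

test_that("version 1 precedence stages its 16-cell space and flags conflicts", {
  v1_rec <- function(following, interest, willing, timeframe) {
    validate_record(make_row(
      fv_following = following, interest_recommendations = interest,
      fv_willing = willing, fv_timeframe = timeframe,
      sso_following = "no", sso_willing = "no", sso_timeframe = "unsure"
    ), version = 1)
  }
  expect_identical(stage_component_v1(v1_rec("yes", "no", "no", "unsure"),
                                      "FV")$stage, "A")
  expect_identical(stage_component_v1(v1_rec("no", "no", "yes", "30_days"),
                                      "FV")$stage, "P")
  res <- stage_component_v1(v1_rec("no", "yes", "yes", "unsure"), "FV")
  expect_identical(res$stage, "A")        # willingness yes under precedence
  expect_match(res$rule, "conflict")      # interest=yes would have said I
  # under the published V1 rules every input is definitively staged by at
  # least two items that disagree, so every trace carries the conflict flag
  # (consistent with this version proving non-functional)
  p_case <- stage_component_v1(v1_rec("no", "no", "no", "unsure"), "FV")
  expect_identical(p_case$stage, "P")
  expect_match(p_case$rule, "^P:interest\\+conflict$")

  # exhaustive: precedence oracle over the 16 combinations
  grid <- expand.grid(following = c("yes", "no"), interest = c("yes", "no"),
                      willing = c("yes", "no"),
                      timeframe = c("30_days", "unsure"),
                      stringsAsFactors = FALSE)
  oracle <- function(f, i, w, t) {
    if (f == "yes") "A"
    else if (i == "no") "P"
    else if (w == "no") "P"
    else if (t == "30_days") "A"
    else "A"  # willingness yes
  }
  got <- vapply(seq_len(nrow(grid)), function(j) {
    stage_component_v1(v1_rec(grid$following[j], grid$interest[j],
                              grid$willing[j], grid$timeframe[j]),
                       "FV")$stage
  }, character(1))
  want <- vapply(seq_len(nrow(grid)), function(j) {
    oracle(grid$following[j], grid$interest[j], grid$willing[j],
           grid$timeframe[j])
  }, character(1))
  expect_identical(got, want)
  counts <- enumerate_response_space(1)
  expect_identical(sum(counts), attr(counts, "space_size"))
  expect_identical(unname(counts[STAGES]),
                   unname(vapply(STAGES, function(s) sum(want == s),
                                 integer(1))))
})

test_that("overall combination matches rank-min (v2-3) and rank-max (v1) oracles", {
  pairs <- expand.grid(fv = STAGES, sso = STAGES, stringsAsFactors = FALSE)
  v3 <- vapply(seq_len(nrow(pairs)), function(i) {
    combine_overall(pairs$fv[i], pairs$sso[i], version = 3)$stage
  }, character(1))
  v3_oracle <- rank_stage(pmin(stage_rank(pairs$fv), stage_rank(pairs$sso)))
  expect_identical(v3, v3_oracle)
  expect_identical(table(factor(v3, STAGES)),
                   table(factor(rep(STAGES, c(5, 3, 1)), STAGES)))

  v1 <- vapply(seq_len(nrow(pairs)), function(i) {
    combine_overall(pairs$fv[i], pairs$sso[i], version = 1)$stage
  }, character(1))
  v1_oracle <- rank_stage(pmax(stage_rank(pairs$fv), stage_rank(pairs$sso)))
  expect_identical(v1, v1_oracle)
  expect_identical(table(factor(v1, STAGES)),
                   table(factor(rep(STAGES, c(1, 3, 5)), STAGES)))

  expect_identical(combine_overall("A", "A", 3)$stage, "A")
  expect_identical(combine_overall("A", "P", 3)$stage, "P")
  expect_identical(combine_overall("I", "A", 3)$stage, "I")
  expect_match(combine_overall("I", "A", 1)$rule, "ambiguous")
})

test_that("stage_household composes the three steps with a full trace", {
  # intention household: inadequate FV, salt over limit, I-qualifying answers
  i_row <- make_row(fruit_daily = "no", salt_g_30d = "601",
                    fv_cooperation = "5", sso_cooperation = "5")
  res <- stage_household(validate_record(i_row), version = 3)
  expect_identical(res$fv_stage, "I")
  expect_identical(res$sso_stage, "I")
  expect_identical(res$overall_stage, "I")
  expect_identical(res$fv_rule, "I:ready")

  # action household: FV daily, all SSO within limits (size 4 defaults)
  a_row <- make_row(salt_g_30d = "600", sugar_g_30d = "3600",
                    oil_ml_30d = "3600")
  res_a <- stage_household(validate_record(a_row))
  expect_identical(c(res_a$fv_stage, res_a$sso_stage, res_a$overall_stage),
                   c("A", "A", "A"))

  # FV daily but salt over limit with P-triggering SSO answers -> overall P
  p_row <- make_row(salt_g_30d = "601", sso_willing = "no")
  res_p <- stage_household(validate_record(p_row))
  expect_identical(res_p$fv_stage, "A")
  expect_identical(res_p$sso_stage, "P")
  expect_identical(res_p$overall_stage, "P")
  expect_identical(res_p$sso_rule, "P:willingness")
  expect_identical(res_p$overall_rule, "overall:min=P")

  # every staged household satisfies the rank-min bound and a 1-rule trace
  sim <- simulate_households(simulation_params(n = 100, seed = 5))
  vt <- validate_table(sim$responses)
  st <- stage_households(vt$records)
  expect_identical(stage_rank(st$overall_stage),
                   pmin(stage_rank(st$fv_stage), stage_rank(st$sso_stage)))
  expect_true(all(grepl("^[PIA]:", st$fv_rule)))
  expect_true(all(grepl("^[PIA]:", st$sso_rule)))
})

test_that("moving any single response toward readiness never lowers the stage", {
  set.seed(23)
  for (i in 1:60) {
    willing <- sample(c(TRUE, FALSE), 1)
    timeframe <- sample(c("immediate", "unsure"), 1)
    confidence <- sample(5, 1)
    cooperation <- sample(5, 1)
    ok <- sample(c(TRUE, FALSE), 1)
    base <- stage_component_v3(ok, willing, timeframe, confidence,
                               cooperation)$stage
    better <- list(
      stage_component_v3(ok, TRUE, timeframe, confidence, cooperation),
      stage_component_v3(ok, willing, "immediate", confidence, cooperation),
      stage_component_v3(ok, willing, timeframe, min(confidence + 1, 5),
                         cooperation),
      stage_component_v3(ok, willing, timeframe, confidence,
                         min(cooperation + 1, 5)),
      stage_component_v3(TRUE, willing, timeframe, confidence, cooperation)
    )
    for (b in better) {
      expect_gte(stage_rank(b$stage), stage_rank(base))
    }
  }
})
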