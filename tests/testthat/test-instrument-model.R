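test_that("stage labels parse, rank and round-trip in any case", {
  expect_identical(parse_stage(c("p", " I", "a ")), c("P", "I", "A"))
  expect_identical(parse_stage(c("Pre-contemplation", "INTENTION", "action")),
                   c("P", "I", "A"))
  expect_identical(stage_rank(c("P", "I", "A")), 0:2)
  expect_true(all(stage_factor(c("P", "A")) == c("P", "A")))
  expect_true(stage_factor("P") < stage_factor("I"))
  for (s in c("P", "i", "A")) {
    expect_identical(parse_stage(parse_stage(s)), toupper(s))
  }
  expect_error(parse_stage("X"), "invalid stage")
  expect_error(rank_stage(3), "rank")
})

test_that("the final schema enumerates 17 items grouped 8/9/15", {
  items <- instrument_items()
  expect_identical(nrow(items), 17L)
  expect_identical(anyDuplicated(items$item), 0L)
  expect_identical(sum(items$fv), 8L)
  expect_identical(sum(items$sso), 9L)
  expect_identical(sum(items$overall), 15L)
  # household size is the only item shared by FV and SSO; the two component
  # stage codes are the items excluded from OVERALL
  expect_identical(items$item[items$fv & items$sso], "household_size")
  expect_setequal(items$item[!items$overall], c("fv_stage", "sso_stage"))
})

test_that("in-range rows validate and out-of-range fields are named", {
  rec <- validate_record(make_row(fv_confidence = "5", fv_cooperation = "4"))
  expect_s3_class(rec, "household_record")
  expect_identical(rec$fv_staging$confidence, 5L)
  expect_identical(rec$household_size, 4L)
  expect_true(rec$fv$fruit_daily)

  expect_error(validate_record(make_row(fv_confidence = "6")), "fv_confidence")
  expect_error(validate_record(make_row(sso_cooperation = "0")),
               "sso_cooperation")
  expect_error(validate_record(make_row(salt_g_30d = "-1")), "salt_g_30d")
  expect_error(validate_record(make_row(oil_ml_30d = "much")), "oil_ml_30d")
  expect_error(validate_record(make_row(household_size = "0")),
               "household_size")
  expect_error(validate_record(make_row(fv_willing = "maybe")), "fv_willing")
})

test_that("required-field sets are enforced per version", {
  # hand-written required-field matrix (column name -> versions requiring it)
  required <- list(
    household_id = 1:3, household_size = 1:3,
    fruit_daily = 3, vegetable_daily = 3,
    fruit_servings = 2, vegetable_servings = 2,
    salt_g_30d = 2:3, sugar_g_30d = 2:3, oil_ml_30d = 2:3,
    fv_willing = 1:3, fv_timeframe = 1:3,
    fv_confidence = 2:3, fv_cooperation = 2:3,
    sso_willing = 1:3, sso_timeframe = 1:3,
    sso_confidence = 2:3, sso_cooperation = 2:3,
    interest_recommendations = 1, fv_following = 1, sso_following = 1
  )
  for (v in 1:3) {
    expect_setequal(required_fields(v),
                    names(required)[vapply(required, function(vs) v %in% vs,
                                           logical(1L))])
  }
  for (field in names(required)) {
    for (v in 1:3) {
      row <- make_row()
      row[field] <- ""
      if (v == 1L) {
        row["fv_timeframe"] <- "30_days"
        row["sso_timeframe"] <- "unsure"
        if (field %in% c("fv_timeframe", "sso_timeframe")) row[field] <- ""
      }
      if (v %in% required[[field]]) {
        expect_error(validate_record(row, version = v), field,
                     label = sprintf("v%d missing %s", v, field))
      } else {
        expect_s3_class(validate_record(row, version = v),
                        "household_record")
      }
    }
  }
})

test_that("timeframe vocabulary is version-specific", {
  expect_error(validate_record(make_row(fv_timeframe = "30_days")),
               "fv_timeframe")
  v1row <- make_row(fv_timeframe = "30 days", sso_timeframe = "unsure")
  rec <- validate_record(v1row, version = 1)
  expect_identical(rec$fv_staging$timeframe, "30_days")
  expect_error(validate_record(make_row(fv_timeframe = "immediate"),
                               version = 1),
               "fv_timeframe")
})

test_that("enumerated fields canonicalise case and whitespace", {
  rec <- validate_record(make_row(fruit_daily = " YES ",
                                  sso_willing = "No",
                                  fv_timeframe = "Immediate"))
  expect_true(rec$fv$fruit_daily)
  expect_false(rec$sso_staging$willingness)
  expect_identical(rec$fv_staging$timeframe, "immediate")
})

test_that("validate_record(format_row(record)) round-trips", {
  sim <- simulate_households(simulation_params(n = 40, seed = 11))
  vt <- validate_table(sim$responses, version = 3)
  for (rec in vt$records[1:15]) {
    expect_identical(validate_record(format_row(rec), version = 3), rec)
  }
})

test_that("strict mode rejects and lenient mode excludes with a count", {
  tab <- make_table(list(make_row(),
                         make_row(household_id = "HH002",
                                  fv_confidence = "9")))
  expect_error(validate_table(tab, mode = "strict"), "fv_confidence")
  vt <- validate_table(tab, mode = "lenient")
  expect_length(vt$records, 1L)
  expect_identical(nrow(vt$excluded), 1L)
  expect_identical(vt$excluded$household_id, "HH002")
  expect_error(validate_table(make_table(list(make_row(), make_row()))),
               "duplicate household_id")
})

test_that("encode_items returns 8/9/15 columns and excludes incomplete rows", {
  sim <- simulate_households(simulation_params(n = 30, seed = 3))
  vt <- validate_table(sim$responses)
  st <- stage_households(vt$records)
  expect_identical(ncol(encode_items(vt$records, st, "FV")), 8L)
  expect_identical(ncol(encode_items(vt$records, st, "SSO")), 9L)
  m <- encode_items(vt$records, st, "OVERALL")
  expect_identical(ncol(m), 15L)
  expect_identical(nrow(m), 30L)
  expect_false(anyNA(m))
  expect_identical(attr(m, "excluded"), 0L)
  # stage codes are on the 0/1/2 scale, indicators on 0/1
  expect_true(all(m[, "overall_stage"] %in% 0:2))
  expect_true(all(m[, "fruit_daily"] %in% 0:1))

  one <- encode_items(vt$records[1], st[1, , drop = FALSE], "SSO")
  expect_identical(dim(one), c(1L, 9L))

  expect_error(encode_items(vt$records, st[-1, ], "FV"), "misaligned")

  # a record missing an FV staging answer drops out of the FV matrix
  # (validated under v1, whose required set does not include cooperation)
  row <- make_row(household_id = "HH999", fv_cooperation = "",
                  fv_timeframe = "30_days", sso_timeframe = "unsure")
  rec2 <- validate_record(row, version = 1)
  recs <- c(vt$records, list(rec2))
  st2 <- rbind(st, stage_households(list(rec2), version = 1))
  m2 <- encode_items(recs, st2, "FV")
  expect_identical(nrow(m2), 30L)
  expect_identical(attr(m2, "excluded"), 1L)
})
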