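# In-code fixtures: raw questionnaire rows built programmatically.

# a fully populated raw row, valid under every algorithm version; override
# individual fields to build test cases
make_row <- function(...) {
  row <- c(
    household_id = "HH001", household_size = "4",
    fruit_daily = "yes", vegetable_daily = "yes",
    fruit_servings = "2", vegetable_servings = "3",
    salt_g_30d = "500", sugar_g_30d = "3000", oil_ml_30d = "3000",
    fv_willing = "yes", fv_timeframe = "immediate",
    fv_confidence = "5", fv_cooperation = "4",
    sso_willing = "yes", sso_timeframe = "immediate",
    sso_confidence = "5", sso_cooperation = "4",
    interest_recommendations = "yes", fv_following = "no",
    sso_following = "no"
  )
  over <- c(...)
  row[names(over)] <- over
  row
}

# rows as a data frame (one row per call argument list)
make_table <- function(rows) {
  do.call(rbind, lapply(rows, function(r) as.data.frame(t(r))))
}

# independent re-statement of the final-version component rules, written
# directly from the prose (used as the enumeration oracle)
oracle_stage_v3 <- function(consumption_ok, willing, timeframe, confidence,
                            cooperation) {
  if (consumption_ok) return("A")
  p <- !willing || timeframe == "unsure" || confidence <= 4 ||
    cooperation <= 3
  if (p) "P" else "I"
}
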