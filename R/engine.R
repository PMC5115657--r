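# Staging engine: per-component and overall household stage-of-change under
# each algorithm version, with a rule trace naming the clause that fired.

# shared staging rules of Versions 2 and 3 (Version 2 differs only in how
# consumption adequacy is assessed upstream, not in the rules themselves)
stage_component_rules <- function(consumption_ok, willingness, timeframe,
                                  confidence, cooperation) {
  stopifnot(is.logical(consumption_ok), length(consumption_ok) == 1L,
            !is.na(consumption_ok))
  if (consumption_ok) {
    return(list(stage = "A", rule = "A:consumption"))
  }
  if (is.na(willingness) || is.na(timeframe) || is.na(confidence) ||
      is.na(cooperation)) {
    stop("staging responses are incomplete and consumption is not adequate",
         call. = FALSE)
  }
  if (!timeframe %in% c("immediate", "unsure")) {
    stop("timeframe must be 'immediate' or 'unsure'", call. = FALSE)
  }
  if (confidence < 1 || confidence > 5 || cooperation < 1 || cooperation > 5) {
    stop("confidence and cooperation must be in 1-5", call. = FALSE)
  }
  # pre-contemplation disqualifiers, checked in documented order; the order
  # affects only the trace, never the stage
  if (!willingness)        return(list(stage = "P", rule = "P:willingness"))
  if (timeframe == "unsure") return(list(stage = "P", rule = "P:timeframe"))
  if (confidence <= 4)     return(list(stage = "P", rule = "P:confidence"))
  if (cooperation <= 3)    return(list(stage = "P", rule = "P:cooperation"))
  list(stage = "I", rule = "I:ready")
}

#' Stage one component under the final (Version 3) algorithm
#'
#' Action if consumption is adequate (daily FV intake, or SSO within
#' limits). Otherwise pre-contemplation if any disqualifier holds: not
#' willing to change, unsure about the timeframe, confidence 1-4, or
#' expected cooperation 1-3. Otherwise intention (willing to change
#' immediately with confidence 5 and cooperation 4-5).
#'
#' @param consumption_ok logical: component consumption adequate
#'   (self-evaluation).
#' @param willingness logical (or yes/no): willing to make changes.
#' @param timeframe `"immediate"` or `"unsure"`.
#' @param confidence,cooperation integers 1-5.
#' @return list with `stage` (`"P"`, `"I"` or `"A"`) and `rule` (identifier
#'   of the single clause that fired).
#' @examples
#' stage_component_v3(FALSE, willingness = "yes", timeframe = "immediate",
#'                    confidence = 5, cooperation = 4)
#' @export
stage_component_v3 <- function(consumption_ok, willingness, timeframe,
                               confidence, cooperation) {
  stage_component_rules(consumption_ok, as_flag(willingness, "willingness"),
                        timeframe, confidence, cooperation)
}

#' Stage one component under the Version 2 algorithm
#'
#' Identical staging rules to [stage_component_v3()]; Version 2 differs only
#' in that FV consumption adequacy is supplied by the serving-based assessor
#' ([assess_fv_servings()]) rather than the daily indicators.
#'
#' @inheritParams stage_component_v3
#' @param consumption_ok logical: adequacy from the serving-based assessor.
#' @return list with `stage` and `rule`.
#' @export
stage_component_v2 <- function(consumption_ok, willingness, timeframe,
                               confidence, cooperation) {
  stage_component_rules(consumption_ok, as_flag(willingness, "willingness"),
                        timeframe, confidence, cooperation)
}

#' Stage one component under the Version 1 algorithm
#'
#' Version 1 used awareness items (interest in the current dietary
#' recommendations and whether the household already follows them) together
#' with willingness and a `30_days`/`unsure` timeframe. Its published rules
#' conflict for some inputs (interest yes maps to I while willingness yes
#' maps to A); this implementation applies a documented precedence and flags
#' every conflicting input in the rule trace with a `+conflict` suffix.
#' Precedence: (1) already following -> A; (2) interest no -> P;
#' (3) willingness no -> P; (4) timeframe 30_days -> A; (5) willingness
#' yes -> A; (6) timeframe unsure -> I; (7) interest yes -> I.
#'
#' @param record a `household_record` validated for version 1.
#' @param component `"FV"` or `"SSO"`.
#' @return list with `stage` and `rule`.
#' @export
stage_component_v1 <- function(record, component = c("FV", "SSO")) {
  component <- match.arg(component)
  following <- if (component == "FV") record$v1$fv_following else
    record$v1$sso_following
  interest <- record$v1$interest
  sr <- if (component == "FV") record$fv_staging else record$sso_staging
  if (is.null(sr) || is.na(following) || is.na(interest) ||
      is.na(sr$willingness) || is.na(sr$timeframe)) {
    stop("version 1 requires interest, following, willingness and timeframe",
         call. = FALSE)
  }
  willingness <- sr$willingness
  timeframe <- sr$timeframe

  # all definitive assignments the published rules would make; >1 distinct
  # stage means the input hits a rule conflict
  assigned <- c(
    if (following) "A",
    if (!interest) "P" else "I",
    if (!willingness) "P" else "A",
    if (timeframe == "30_days") "A" else "I"
  )
  conflict <- length(unique(assigned)) > 1L

  out <- if (following) {
    list(stage = "A", rule = "A:following")
  } else if (!interest) {
    list(stage = "P", rule = "P:interest")
  } else if (!willingness) {
    list(stage = "P", rule = "P:willingness")
  } else if (timeframe == "30_days") {
    list(stage = "A", rule = "A:timeframe")
  } else if (willingness) {
    list(stage = "A", rule = "A:willingness")
  } else if (timeframe == "unsure") {
    list(stage = "I", rule = "I:timeframe")
  } else {
    list(stage = "I", rule = "I:interest")
  }
  if (conflict) out$rule <- paste0(out$rule, "+conflict")
  out
}

#' Combine component stages into the overall household stage
#'
#' Versions 2 and 3 take the lower (rank-minimum) of the FV and SSO stages,
#' so the household is in action only if both components are. Version 1
#' combined the other way (pre-contemplation only if both components are P),
#' implemented as the rank-maximum; its published rules are ambiguous for
#' an (I, A) pair, resolved A-dominant and flagged `+ambiguous` in the
#' trace.
#'
#' @param fv_stage,sso_stage component stage labels.
#' @param version algorithm version, 1, 2 or 3.
#' @return list with `stage` and `rule`.
#' @examples
#' combine_overall("A", "P", version = 3)
#' @export
combine_overall <- function(fv_stage, sso_stage, version = 3) {
  version <- check_version(version)
  rf <- stage_rank(fv_stage)
  rs <- stage_rank(sso_stage)
  if (version == 1L) {
    stage <- rank_stage(max(rf, rs))
    rule <- paste0("overall:max=", stage)
    if (setequal(c(parse_stage(fv_stage), parse_stage(sso_stage)),
                 c("I", "A"))) {
      rule <- paste0(rule, "+ambiguous")
    }
  } else {
    stage <- rank_stage(min(rf, rs))
    rule <- paste0("overall:min=", stage)
  }
  list(stage = stage, rule = rule)
}

#' Stage one household
#'
#' Runs the instrument's three-step algorithm on a validated record:
#' step 1 computes the FV stage, step 2 the SSO stage (each from the
#' consumption self-evaluation and the staging questions), and step 3
#' combines them into the overall household stage. The result carries a
#' rule trace naming the clause that fired for each component.
#'
#' @param record a `household_record` (see [validate_record()]).
#' @param version algorithm version, 1, 2 or 3 (default 3).
#' @param config a run configuration (see [default_config()]) supplying the
#'   limits chart and the adequacy policies.
#' @return a `stage_result`: list with `household_id`, `version`,
#'   `fv_stage`, `sso_stage`, `overall_stage` and the three rule
#'   identifiers.
#' @examples
#' row <- c(household_id = "HH1", household_size = "2",
#'   fruit_daily = "yes", vegetable_daily = "yes",
#'   salt_g_30d = "300", sugar_g_30d = "1800", oil_ml_30d = "1800",
#'   fv_willing = "yes", fv_timeframe = "immediate",
#'   fv_confidence = "5", fv_cooperation = "5",
#'   sso_willing = "yes", sso_timeframe = "immediate",
#'   sso_confidence = "5", sso_cooperation = "5")
#' stage_household(validate_record(row))$overall_stage
#' @export
stage_household <- function(record, version = 3, config = default_config()) {
  stopifnot(inherits(record, "household_record"))
  version <- check_version(version)
  pol <- config$policies

  if (version == 1L) {
    fv <- stage_component_v1(record, "FV")
    sso <- stage_component_v1(record, "SSO")
  } else {
    fv_ok <- if (version == 3L) {
      assess_fv_daily(record$fv$fruit_daily, record$fv$vegetable_daily,
                      policy = pol$fv_daily_rule)
    } else {
      assess_fv_servings(record$fv$fruit_servings,
                         record$fv$vegetable_servings,
                         fruit_target = pol$fruit_target,
                         veg_target = pol$veg_target)
    }
    sso_ok <- assess_sso(record$sso$salt_30d, record$sso$sugar_30d,
                         record$sso$oil_30d, record$household_size,
                         chart = config$chart,
                         aggregation = pol$sso_rule)$sso_within
    stage_fun <- if (version == 3L) stage_component_v3 else stage_component_v2
    fv <- stage_fun(fv_ok, record$fv_staging$willingness,
                    record$fv_staging$timeframe,
                    record$fv_staging$confidence,
                    record$fv_staging$cooperation)
    sso <- stage_fun(sso_ok, record$sso_staging$willingness,
                     record$sso_staging$timeframe,
                     record$sso_staging$confidence,
                     record$sso_staging$cooperation)
  }
  overall <- combine_overall(fv$stage, sso$stage, version)

  # structural invariant of the combine step
  comb <- if (version == 1L) max else min
  stopifnot(stage_rank(overall$stage) ==
              comb(stage_rank(fv$stage), stage_rank(sso$stage)))

  structure(list(
    household_id = record$household_id,
    version = version,
    fv_stage = fv$stage, sso_stage = sso$stage,
    overall_stage = overall$stage,
    fv_rule = fv$rule, sso_rule = sso$rule, overall_rule = overall$rule
  ), class = "stage_result")
}

#' Stage a list of households
#'
#' @param records list of `household_record`.
#' @param version algorithm version (default 3).
#' @param config run configuration (see [default_config()]).
#' @return data frame with one row per household: `household_id`, `version`,
#'   `fv_stage`, `sso_stage`, `overall_stage`, `fv_rule`, `sso_rule`,
#'   `overall_rule`.
#' @export
stage_households <- function(records, version = 3,
                             config = default_config()) {
  rows <- lapply(records, function(r) {
    as.data.frame(unclass(stage_household(r, version, config)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enumerate the staging-response space
#'
#' Exhaustively stages every combination of the discrete staging responses
#' for one component and tallies the resulting stages. For Versions 2-3
#' with inadequate consumption the 2 x 2 x 5 x 5 = 100 combinations split
#' 98 P / 2 I (the two I cells are confidence 5 with cooperation 4 or 5
#' under willing + immediate); with adequate consumption all 100 are A.
#' For Version 1 the space is the 16 combinations of
#' following x interest x willingness x timeframe.
#'
#' @param version algorithm version, 1, 2 or 3.
#' @param consumption_ok logical, adequacy flag fed to Versions 2-3
#'   (ignored for Version 1).
#' @return named integer vector `c(P=, I=, A=)` with attribute
#'   `space_size`.
#' @examples
#' enumerate_response_space(3, consumption_ok = FALSE)
#' @export
enumerate_response_space <- function(version = 3, consumption_ok = FALSE) {
  version <- check_version(version)
  if (version >= 2L) {
    grid <- expand.grid(
      willingness = c(TRUE, FALSE),
      timeframe = c("immediate", "unsure"),
      confidence = 1:5, cooperation = 1:5,
      stringsAsFactors = FALSE
    )
    stages <- vapply(seq_len(nrow(grid)), function(i) {
      stage_component_rules(consumption_ok, grid$willingness[i],
                            grid$timeframe[i], grid$confidence[i],
                            grid$cooperation[i])$stage
    }, character(1L))
  } else {
    grid <- expand.grid(
      following = c(TRUE, FALSE), interest = c(TRUE, FALSE),
      willingness = c(TRUE, FALSE), timeframe = c("30_days", "unsure"),
      stringsAsFactors = FALSE
    )
    stages <- vapply(seq_len(nrow(grid)), function(i) {
      rec <- structure(list(
        household_id = "enum", household_size = 1L,
        fv = list(), sso = list(),
        fv_staging = list(willingness = grid$willingness[i],
                          timeframe = grid$timeframe[i],
                          confidence = NA_integer_,
                          cooperation = NA_integer_),
        sso_staging = NULL,
        v1 = list(interest = grid$interest[i],
                  fv_following = grid$following[i], sso_following = NA),
        version = 1L
      ), class = "household_record")
      stage_component_v1(rec, "FV")$stage
    }, character(1L))
  }
  counts <- vapply(STAGES, function(s) sum(stages == s), integer(1L))
  structure(counts, space_size = nrow(grid))
}
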