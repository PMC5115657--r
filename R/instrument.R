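# Instrument data model: the 17-item final schema, record validation for the
# three algorithm versions, and numeric item coding for reliability analysis.

RESPONSE_COLUMNS <- c(
  "household_id", "household_size",
  "fruit_daily", "vegetable_daily", "fruit_servings", "vegetable_servings",
  "salt_g_30d", "sugar_g_30d", "oil_ml_30d",
  "fv_willing", "fv_timeframe", "fv_confidence", "fv_cooperation",
  "sso_willing", "sso_timeframe", "sso_confidence", "sso_cooperation",
  "interest_recommendations", "fv_following", "sso_following"
)

#' The 17-item final instrument schema
#'
#' Enumerates the distinct items of the final (Version 3) instrument:
#' consumption estimation (2 FV + 3 SSO items), staging questions
#' (4 FV + 4 SSO items), household size (1 common item) and stage
#' computation (FV, SSO and overall stage: 3 items). Logical columns mark
#' membership in the three reliability groups: FV (8 items), SSO (9 items)
#' and OVERALL (15 items; the two per-component stage-computation items are
#' excluded, household size is shared by all groups).
#'
#' @return data frame with columns `item`, `section`, `fv`, `sso`, `overall`.
#' @examples
#' colSums(instrument_items()[c("fv", "sso", "overall")])
#' @export
instrument_items <- function() {
  it <- function(item, section, fv, sso, overall) {
    data.frame(item = item, section = section, fv = fv, sso = sso,
               overall = overall)
  }
  out <- rbind(
    it("fruit_daily",      "estimation", TRUE,  FALSE, TRUE),
    it("vegetable_daily",  "estimation", TRUE,  FALSE, TRUE),
    it("salt_g_30d",       "estimation", FALSE, TRUE,  TRUE),
    it("sugar_g_30d",      "estimation", FALSE, TRUE,  TRUE),
    it("oil_ml_30d",       "estimation", FALSE, TRUE,  TRUE),
    it("fv_willing",       "staging",    TRUE,  FALSE, TRUE),
    it("fv_timeframe",     "staging",    TRUE,  FALSE, TRUE),
    it("fv_confidence",    "staging",    TRUE,  FALSE, TRUE),
    it("fv_cooperation",   "staging",    TRUE,  FALSE, TRUE),
    it("sso_willing",      "staging",    FALSE, TRUE,  TRUE),
    it("sso_timeframe",    "staging",    FALSE, TRUE,  TRUE),
    it("sso_confidence",   "staging",    FALSE, TRUE,  TRUE),
    it("sso_cooperation",  "staging",    FALSE, TRUE,  TRUE),
    it("household_size",   "household",  TRUE,  TRUE,  TRUE),
    it("fv_stage",         "stage",      TRUE,  FALSE, FALSE),
    it("sso_stage",        "stage",      FALSE, TRUE,  FALSE),
    it("overall_stage",    "stage",      FALSE, FALSE, TRUE)
  )
  stopifnot(nrow(out) == 17L,
            sum(out$fv) == 8L, sum(out$sso) == 9L, sum(out$overall) == 15L,
            sum(out$fv) + sum(out$sso) - 2L == sum(out$overall))
  out
}

#' Required response fields by algorithm version
#'
#' @param version algorithm version, 1, 2 or 3.
#' @return character vector of required `responses.csv` column names.
#' @export
required_fields <- function(version) {
  version <- check_version(version)
  common <- c("household_id", "household_size")
  staging <- c("fv_willing", "fv_timeframe", "fv_confidence", "fv_cooperation",
               "sso_willing", "sso_timeframe", "sso_confidence",
               "sso_cooperation")
  sso <- c("salt_g_30d", "sugar_g_30d", "oil_ml_30d")
  switch(as.character(version),
    "1" = c(common, "fv_willing", "fv_timeframe", "sso_willing",
            "sso_timeframe", "interest_recommendations", "fv_following",
            "sso_following"),
    "2" = c(common, "fruit_servings", "vegetable_servings", sso, staging),
    "3" = c(common, "fruit_daily", "vegetable_daily", sso, staging)
  )
}

check_version <- function(version) {
  version <- as.integer(version)
  if (length(version) != 1L || is.na(version) || !version %in% 1:3) {
    stop("version must be 1, 2 or 3", call. = FALSE)
  }
  version
}

timeframe_domain <- function(version) {
  if (version == 1L) c("30_days", "unsure") else c("immediate", "unsure")
}

is_blank <- function(x) is.null(x) || is.na(x) || trimws(as.character(x)) == ""

record_error <- function(id, field, msg) {
  stop(sprintf("household '%s', field '%s': %s", id, field, msg),
       call. = FALSE)
}

parse_scale5 <- function(x, id, field) {
  v <- suppressWarnings(as.numeric(trimws(x)))
  if (is.na(v) || v != round(v) || v < 1 || v > 5) {
    record_error(id, field, sprintf("expected an integer 1-5, got '%s'", x))
  }
  as.integer(v)
}

parse_quantity <- function(x, id, field) {
  v <- suppressWarnings(as.numeric(trimws(x)))
  if (is.na(v) || !is.finite(v)) {
    record_error(id, field, sprintf("unparseable numeric '%s'", x))
  }
  if (v < 0) record_error(id, field, "must be >= 0")
  v
}

parse_yesno <- function(x, id, field) {
  out <- tryCatch(as_flag(x, field), error = function(e) NULL)
  if (is.null(out)) {
    record_error(id, field, sprintf("expected yes/no, got '%s'", x))
  }
  out
}

parse_timeframe <- function(x, id, field, version) {
  dom <- timeframe_domain(version)
  v <- gsub("[ -]", "_", tolower(trimws(as.character(x))))
  if (v %in% c("not_sure", "notsure")) v <- "unsure"
  if (!v %in% dom) {
    record_error(id, field, sprintf("expected one of %s, got '%s'",
                                    paste(dom, collapse = "/"), x))
  }
  v
}

#' Validate one questionnaire row into a typed household record
#'
#' Canonicalises and type-checks a single raw row (field name to string map)
#' from a responses table. The required-field set depends on the algorithm
#' version: Version 3 needs the daily FV indicators, the SSO quantities,
#' household size and both four-item staging blocks; Version 2 replaces the
#' daily indicators with 24-hour serving counts; Version 1 needs the
#' interest/already-following items plus the willingness and timeframe
#' staging items (timeframe domain `30_days`/`unsure` instead of
#' `immediate`/`unsure`). Optional fields present in the row are parsed too.
#'
#' @param raw_row named list, named character vector or one-row data frame.
#' @param version algorithm version, 1, 2 or 3 (default 3).
#' @return a `household_record`: list with `household_id`, `household_size`,
#'   `fv`, `sso`, `fv_staging`, `sso_staging`, `v1` and `version` elements.
#' @examples
#' row <- c(household_id = "HH1", household_size = "4",
#'   fruit_daily = "yes", vegetable_daily = "no",
#'   salt_g_30d = "700", sugar_g_30d = "3000", oil_ml_30d = "3100",
#'   fv_willing = "yes", fv_timeframe = "immediate",
#'   fv_confidence = "5", fv_cooperation = "4",
#'   sso_willing = "no", sso_timeframe = "unsure",
#'   sso_confidence = "2", sso_cooperation = "3")
#' validate_record(row, version = 3)$fv_staging
#' @export
validate_record <- function(raw_row, version = 3) {
  version <- check_version(version)
  if (is.data.frame(raw_row)) {
    stopifnot(nrow(raw_row) == 1L)
    raw_row <- as.list(raw_row)
  }
  raw_row <- lapply(as.list(raw_row), function(x) {
    if (length(x) == 0L) NA_character_ else as.character(x)[1L]
  })
  id <- if (is_blank(raw_row$household_id)) "<unknown>" else {
    trimws(raw_row$household_id)
  }

  req <- required_fields(version)
  have <- names(raw_row)[!vapply(raw_row, is_blank, logical(1L))]
  missing <- setdiff(req, have)
  if (length(missing) > 0L) {
    record_error(id, missing[1L], "missing required field")
  }

  get <- function(field) if (field %in% have) raw_row[[field]] else NA

  size <- parse_quantity(raw_row$household_size, id, "household_size")
  if (size != round(size) || size < 1) {
    record_error(id, "household_size", "must be an integer >= 1")
  }

  opt_flag <- function(f) if (f %in% have) parse_yesno(get(f), id, f) else NA
  opt_qty <- function(f) if (f %in% have) parse_quantity(get(f), id, f) else NA_real_

  staging_block <- function(prefix) {
    fields <- paste0(prefix, c("_willing", "_timeframe", "_confidence",
                               "_cooperation"))
    if (!any(fields %in% have)) return(NULL)
    list(
      willingness = if (fields[1L] %in% have)
        parse_yesno(get(fields[1L]), id, fields[1L]) else NA,
      timeframe = if (fields[2L] %in% have)
        parse_timeframe(get(fields[2L]), id, fields[2L], version) else
          NA_character_,
      confidence = if (fields[3L] %in% have)
        parse_scale5(get(fields[3L]), id, fields[3L]) else NA_integer_,
      cooperation = if (fields[4L] %in% have)
        parse_scale5(get(fields[4L]), id, fields[4L]) else NA_integer_
    )
  }

  rec <- list(
    household_id = id,
    household_size = as.integer(size),
    fv = list(
      fruit_daily = opt_flag("fruit_daily"),
      vegetable_daily = opt_flag("vegetable_daily"),
      fruit_servings = opt_qty("fruit_servings"),
      vegetable_servings = opt_qty("vegetable_servings")
    ),
    sso = list(
      salt_30d = opt_qty("salt_g_30d"),
      sugar_30d = opt_qty("sugar_g_30d"),
      oil_30d = opt_qty("oil_ml_30d")
    ),
    fv_staging = staging_block("fv"),
    sso_staging = staging_block("sso"),
    v1 = list(
      interest = opt_flag("interest_recommendations"),
      fv_following = opt_flag("fv_following"),
      sso_following = opt_flag("sso_following")
    ),
    version = version
  )
  class(rec) <- "household_record"
  rec
}

#' Format a household record back into a raw response row
#'
#' Inverse of [validate_record()]: produces a named character vector using
#' the `responses.csv` column set, with `yes`/`no` flags and empty strings
#' for absent optional fields. `validate_record(format_row(r))` reproduces
#' `r` for any valid record.
#'
#' @param record a `household_record`.
#' @return named character vector over the full response column set.
#' @export
format_row <- function(record) {
  stopifnot(inherits(record, "household_record"))
  fmt_flag <- function(x) {
    if (is.na(x)) "" else if (x) "yes" else "no"
  }
  fmt_num <- function(x) if (is.na(x)) "" else format(x, scientific = FALSE)
  fmt_chr <- function(x) if (is.na(x)) "" else x
  sb <- function(block, what) {
    if (is.null(block)) "" else switch(what,
      willing = fmt_flag(block$willingness),
      timeframe = fmt_chr(block$timeframe),
      confidence = fmt_num(block$confidence),
      cooperation = fmt_num(block$cooperation))
  }
  out <- c(
    household_id = record$household_id,
    household_size = fmt_num(record$household_size),
    fruit_daily = fmt_flag(record$fv$fruit_daily),
    vegetable_daily = fmt_flag(record$fv$vegetable_daily),
    fruit_servings = fmt_num(record$fv$fruit_servings),
    vegetable_servings = fmt_num(record$fv$vegetable_servings),
    salt_g_30d = fmt_num(record$sso$salt_30d),
    sugar_g_30d = fmt_num(record$sso$sugar_30d),
    oil_ml_30d = fmt_num(record$sso$oil_30d),
    fv_willing = sb(record$fv_staging, "willing"),
    fv_timeframe = sb(record$fv_staging, "timeframe"),
    fv_confidence = sb(record$fv_staging, "confidence"),
    fv_cooperation = sb(record$fv_staging, "cooperation"),
    sso_willing = sb(record$sso_staging, "willing"),
    sso_timeframe = sb(record$sso_staging, "timeframe"),
    sso_confidence = sb(record$sso_staging, "confidence"),
    sso_cooperation = sb(record$sso_staging, "cooperation"),
    interest_recommendations = fmt_flag(record$v1$interest),
    fv_following = fmt_flag(record$v1$fv_following),
    sso_following = fmt_flag(record$v1$sso_following)
  )
  out[RESPONSE_COLUMNS]
}

#' Validate a responses table
#'
#' Validates every row of a raw responses table. In strict mode (default)
#' the first invalid row aborts with an error naming the household and
#' field. In lenient mode invalid rows are excluded (the household is left
#' unstaged) and reported in the `excluded` element.
#'
#' @param df data frame of raw response strings (e.g. from
#'   [read_responses()]).
#' @param version algorithm version, 1, 2 or 3.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return list with `records` (list of `household_record`) and `excluded`
#'   (data frame of `household_id`, `message` for rejected rows).
#' @export
validate_table <- function(df, version = 3, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  version <- check_version(version)
  if (!is.data.frame(df) || nrow(df) == 0L) {
    stop("no households: the responses table is empty", call. = FALSE)
  }
  ids <- trimws(as.character(df$household_id))
  if (anyDuplicated(ids[nzchar(ids)])) {
    stop("duplicate household_id in responses table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  records <- vector("list", nrow(df))
  excluded <- list()
  for (i in seq_len(nrow(df))) {
    res <- tryCatch(validate_record(df[i, , drop = FALSE], version),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (mode == "strict") stop(res)
      excluded[[length(excluded) + 1L]] <-
        data.frame(household_id = ids[i], message = conditionMessage(res))
    } else {
      records[[i]] <- res
    }
  }
  records <- records[!vapply(records, is.null, logical(1L))]
  excluded <- if (length(excluded) > 0L) {
    do.call(rbind, excluded)
  } else {
    data.frame(household_id = character(), message = character())
  }
  list(records = records, excluded = excluded)
}

#' Encode items numerically for reliability analysis
#'
#' Builds the numeric item matrix for one reliability group so Cronbach's
#' alpha can be computed on it. Default coding: binary items 0/1; timeframe
#' `immediate` = 1 / `unsure` = 0; confidence and cooperation on their raw
#' 1-5 scale; SSO consumption quantities as within-limit indicators (0/1)
#' and FV consumption as daily indicators (0/1); stage codes 0/1/2;
#' household size as its integer value. The FV group has 8 columns, SSO 9
#' and OVERALL 15 (8 + 9 minus the shared household-size column and the two
#' per-component stage codes).
#'
#' Households with a missing value in any required item are excluded; the
#' exclusion count is attached as the `"excluded"` attribute.
#'
#' @param records list of `household_record` (see [validate_table()]).
#' @param results stage-results data frame from [stage_households()],
#'   aligned with `records` by `household_id`.
#' @param group `"FV"`, `"SSO"` or `"OVERALL"`.
#' @param chart limits chart used for the SSO within-limit indicators.
#' @param sso_rule aggregation for `sso_within` (unused by the indicators
#'   themselves, which are per-component).
#' @return numeric matrix (class `item_matrix`) with one row per household
#'   and the group's items as columns; attributes `group` and `excluded`.
#' @export
encode_items <- function(records, results, group = c("FV", "SSO", "OVERALL"),
                         chart = default_limits_chart(),
                         sso_rule = c("all", "any")) {
  group <- match.arg(group)
  sso_rule <- match.arg(sso_rule)
  ids <- vapply(records, function(r) r$household_id, character(1L))
  if (!setequal(ids, results$household_id) || length(ids) != nrow(results)) {
    stop("records and stage results are misaligned by household_id",
         call. = FALSE)
  }
  results <- results[match(ids, results$household_id), , drop = FALSE]

  flag01 <- function(x) ifelse(is.na(x), NA_real_, as.numeric(x))
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    sso_flags <- if (all(!is.na(unlist(r$sso)))) {
      assess_sso(r$sso$salt_30d, r$sso$sugar_30d, r$sso$oil_30d,
                 r$household_size, chart, aggregation = sso_rule)
    } else {
      data.frame(salt_within = NA, sugar_within = NA, oil_within = NA)
    }
    sblock <- function(b) {
      if (is.null(b)) rep(NA_real_, 4L) else c(
        flag01(b$willingness),
        if (is.na(b$timeframe)) NA_real_ else
          as.numeric(b$timeframe == "immediate"),
        as.numeric(b$confidence), as.numeric(b$cooperation))
    }
    c(
      fruit_daily = flag01(r$fv$fruit_daily),
      vegetable_daily = flag01(r$fv$vegetable_daily),
      salt_within = flag01(sso_flags$salt_within),
      sugar_within = flag01(sso_flags$sugar_within),
      oil_within = flag01(sso_flags$oil_within),
      fv_willing = sblock(r$fv_staging)[1L],
      fv_timeframe = sblock(r$fv_staging)[2L],
      fv_confidence = sblock(r$fv_staging)[3L],
      fv_cooperation = sblock(r$fv_staging)[4L],
      sso_willing = sblock(r$sso_staging)[1L],
      sso_timeframe = sblock(r$sso_staging)[2L],
      sso_confidence = sblock(r$sso_staging)[3L],
      sso_cooperation = sblock(r$sso_staging)[4L],
      household_size = as.numeric(r$household_size),
      fv_stage = as.numeric(stage_rank(results$fv_stage[i])),
      sso_stage = as.numeric(stage_rank(results$sso_stage[i])),
      overall_stage = as.numeric(stage_rank(results$overall_stage[i]))
    )
  })
  full <- do.call(rbind, rows)
  rownames(full) <- ids

  items <- instrument_items()
  cols <- switch(group, FV = items$item[items$fv],
                 SSO = items$item[items$sso],
                 OVERALL = items$item[items$overall])
  # the SSO estimation items enter as within-limit indicators
  cols <- sub("^salt_g_30d$", "salt_within", cols)
  cols <- sub("^sugar_g_30d$", "sugar_within", cols)
  cols <- sub("^oil_ml_30d$", "oil_within", cols)
  stopifnot(length(cols) == c(FV = 8L, SSO = 9L, OVERALL = 15L)[[group]])

  m <- full[, cols, drop = FALSE]
  complete <- stats::complete.cases(m)
  out <- m[complete, , drop = FALSE]
  structure(out, class = c("item_matrix", class(out)),
            group = group, excluded = sum(!complete))
}
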