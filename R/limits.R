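# Consumption-adequacy rules: FV daily/serving indicators and the
# household-size-indexed 30-day salt/sugar/oil (SSO) limits chart.

#' Construct a salt/sugar/oil limits chart
#'
#' A limits chart maps household size to recommended maximum 30-day
#' consumption of salt (g), sugar (g) and oil (ml). Sizes must cover
#' `1:max(size)` contiguously; limits must be positive and non-decreasing
#' in household size.
#'
#' @param household_size integer vector of household sizes covered.
#' @param salt_g_30d,sugar_g_30d,oil_ml_30d numeric vectors of 30-day limits,
#'   aligned with `household_size`.
#' @return a `limits_chart` (data frame with the four columns above).
#' @seealso [default_limits_chart()], [lookup_limits()]
#' @export
limits_chart <- function(household_size, salt_g_30d, sugar_g_30d, oil_ml_30d) {
  size <- as.integer(household_size)
  chart <- data.frame(
    household_size = size,
    salt_g_30d = as.numeric(salt_g_30d),
    sugar_g_30d = as.numeric(sugar_g_30d),
    oil_ml_30d = as.numeric(oil_ml_30d)
  )
  if (nrow(chart) == 0L) stop("limits chart is empty", call. = FALSE)
  chart <- chart[order(chart$household_size), , drop = FALSE]
  if (!identical(chart$household_size, seq_len(nrow(chart)))) {
    stop("limits chart must cover household sizes 1..max contiguously",
         call. = FALSE)
  }
  lim <- as.matrix(chart[, -1L])
  if (any(!is.finite(lim)) || any(lim <= 0)) {
    stop("all limits must be finite and > 0", call. = FALSE)
  }
  if (nrow(chart) > 1L && any(apply(lim, 2L, diff) < 0)) {
    stop("limits must be non-decreasing in household size", call. = FALSE)
  }
  rownames(chart) <- NULL
  class(chart) <- c("limits_chart", "data.frame")
  chart
}

#' Default per-capita limits chart
#'
#' Ships a linear per-capita chart: daily 5 g salt, 30 g sugar and 30 ml oil
#' per person, times 30 days, times household size (so a one-person household
#' gets 150 g / 900 g / 900 ml per 30 days). This default is a configuration
#' placeholder for deployments without a locally calibrated chart; any real
#' deployment should supply its own chart file (see [read_config()]).
#'
#' @param max_size largest household size listed explicitly (default 10);
#'   larger households are handled by per-capita extrapolation in
#'   [lookup_limits()].
#' @param salt_daily_g,sugar_daily_g,oil_daily_ml per-capita daily amounts.
#' @return a `limits_chart`.
#' @examples
#' default_limits_chart()[1:3, ]
#' @export
default_limits_chart <- function(max_size = 10L, salt_daily_g = 5,
                                 sugar_daily_g = 30, oil_daily_ml = 30) {
  size <- seq_len(max_size)
  limits_chart(
    household_size = size,
    salt_g_30d = 30 * salt_daily_g * size,
    sugar_g_30d = 30 * sugar_daily_g * size,
    oil_ml_30d = 30 * oil_daily_ml * size
  )
}

#' Look up 30-day SSO limits for a household size
#'
#' Sizes up to the chart's maximum use the listed entry. Larger households
#' are extrapolated per-capita from the largest entry
#' (`limit * size / max_size`), rounded to 1 g (or ml).
#'
#' @param chart a [limits_chart()].
#' @param household_size integer vector of sizes (>= 1).
#' @return data frame with columns `salt_g_30d`, `sugar_g_30d`, `oil_ml_30d`,
#'   one row per requested size.
#' @examples
#' lookup_limits(default_limits_chart(), c(1, 4, 20))
#' @export
lookup_limits <- function(chart, household_size) {
  if (!inherits(chart, "limits_chart")) {
    chart <- limits_chart(chart$household_size, chart$salt_g_30d,
                          chart$sugar_g_30d, chart$oil_ml_30d)
  }
  size <- as.integer(household_size)
  if (any(is.na(size) | size < 1L)) {
    stop("household_size must be an integer >= 1", call. = FALSE)
  }
  max_size <- max(chart$household_size)
  idx <- pmin(size, max_size)
  out <- chart[idx, c("salt_g_30d", "sugar_g_30d", "oil_ml_30d"),
               drop = FALSE]
  over <- size > max_size
  if (any(over)) {
    scale <- size[over] / max_size
    out[over, ] <- round(out[over, , drop = FALSE] * scale)
  }
  rownames(out) <- NULL
  out
}

# yes/no (any case) or logical -> logical; NA passes through
as_flag <- function(x, field = "value") {
  if (is.logical(x)) return(x)
  s <- tolower(trimws(as.character(x)))
  out <- ifelse(s %in% c("yes", "y", "true", "1"), TRUE,
                ifelse(s %in% c("no", "n", "false", "0"), FALSE, NA))
  out[is.na(x) | s == ""] <- NA
  bad <- is.na(out) & !(is.na(x) | s == "")
  if (any(bad)) {
    stop(sprintf("field '%s': expected yes/no, got '%s'", field,
                 paste(unique(x[bad]), collapse = "', '")), call. = FALSE)
  }
  out
}

#' Assess daily fruit-and-vegetable adequacy
#'
#' Final-version (daily-indicator) adequacy rule. Under the default `"both"`
#' policy a household is adequate only if it consumes both fruit and
#' vegetables daily; `"either"` accepts one of the two.
#'
#' @param fruit_daily,vegetable_daily logical (or yes/no) vectors.
#' @param policy `"both"` (default) or `"either"`.
#' @return logical vector: `TRUE` if FV intake is adequate.
#' @examples
#' assess_fv_daily("yes", "yes")
#' assess_fv_daily("yes", "no", policy = "either")
#' @export
assess_fv_daily <- function(fruit_daily, vegetable_daily,
                            policy = c("both", "either")) {
  policy <- match.arg(policy)
  f <- as_flag(fruit_daily, "fruit_daily")
  v <- as_flag(vegetable_daily, "vegetable_daily")
  if (anyNA(f) || anyNA(v)) {
    stop("fruit_daily and vegetable_daily must both be present", call. = FALSE)
  }
  if (policy == "both") f & v else f | v
}

#' Assess FV adequacy from 24-hour servings
#'
#' Serving-based adequacy rule used by the earlier instrument versions:
#' the daily recommendation of five servings, split as two fruit plus three
#' vegetable servings. Adequate iff both targets are met.
#'
#' @param fruit_servings,vegetable_servings non-negative serving counts over
#'   the previous 24 hours.
#' @param fruit_target,veg_target serving targets (defaults 2 and 3).
#' @return logical vector: `TRUE` if servings meet both targets.
#' @examples
#' assess_fv_servings(2, 3)
#' assess_fv_servings(5, 0)
#' @export
assess_fv_servings <- function(fruit_servings, vegetable_servings,
                               fruit_target = 2, veg_target = 3) {
  f <- suppressWarnings(as.numeric(fruit_servings))
  v <- suppressWarnings(as.numeric(vegetable_servings))
  if (anyNA(f) || anyNA(v)) {
    stop("servings are absent; use the daily-indicator rule (assess_fv_daily)",
         call. = FALSE)
  }
  if (any(f < 0) || any(v < 0)) {
    stop("servings must be >= 0", call. = FALSE)
  }
  f >= fruit_target & v >= veg_target
}

#' Assess household SSO consumption against the limits chart
#'
#' Each component flag is `consumption <= limit` (the boundary counts as
#' within limits). The combined `sso_within` flag aggregates the three
#' component flags: `"all"` (default) requires all three within, `"any"`
#' accepts one.
#'
#' @param salt_g_30d,sugar_g_30d,oil_ml_30d 30-day household consumption
#'   (grams, grams, millilitres); non-negative.
#' @param household_size integer vector of household sizes.
#' @param chart a [limits_chart()]; defaults to [default_limits_chart()].
#' @param aggregation `"all"` (default) or `"any"`.
#' @return data frame with logical columns `salt_within`, `sugar_within`,
#'   `oil_within`, `sso_within`.
#' @examples
#' assess_sso(150, 900, 900, household_size = 1)
#' @export
assess_sso <- function(salt_g_30d, sugar_g_30d, oil_ml_30d, household_size,
                       chart = default_limits_chart(),
                       aggregation = c("all", "any")) {
  aggregation <- match.arg(aggregation)
  cons <- cbind(salt = as.numeric(salt_g_30d),
                sugar = as.numeric(sugar_g_30d),
                oil = as.numeric(oil_ml_30d))
  if (any(!is.finite(cons)) || any(cons < 0)) {
    stop("SSO quantities must be finite and >= 0", call. = FALSE)
  }
  lim <- lookup_limits(chart, rep_len(household_size, nrow(cons)))
  within <- cons <= as.matrix(lim)
  sso <- if (aggregation == "all") {
    within[, 1L] & within[, 2L] & within[, 3L]
  } else {
    within[, 1L] | within[, 2L] | within[, 3L]
  }
  data.frame(
    salt_within = within[, 1L],
    sugar_within = within[, 2L],
    oil_within = within[, 3L],
    sso_within = unname(sso)
  )
}
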