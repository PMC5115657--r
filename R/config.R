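# Run configuration: limits chart plus scoring policies, loadable from a
# YAML or JSON file and validated fail-fast before any computation.

default_policies <- function() {
  list(
    fv_daily_rule = "both",   # both|either daily FV indicators
    sso_rule = "all",         # all|any SSO components within limits
    fruit_target = 2,         # serving targets for the Version 1-2 path
    veg_target = 3,
    missing = "strict"        # strict|lenient missing-data handling
  )
}

#' Default run configuration
#'
#' Bundles the shipped per-capita limits chart (see
#' [default_limits_chart()]) with the default scoring policies: FV daily
#' adequacy requires both indicators, SSO adequacy requires all three
#' components within limits, serving targets 2 fruit + 3 vegetable, and
#' strict missing-data handling.
#'
#' @param chart a [limits_chart()]; defaults to [default_limits_chart()].
#' @param policies named list overriding individual default policies.
#' @return a `run_config` list with elements `chart` and `policies`.
#' @export
default_config <- function(chart = default_limits_chart(),
                           policies = list()) {
  pol <- default_policies()
  unknown <- setdiff(names(policies), names(pol))
  if (length(unknown) > 0L) {
    stop("unknown policy option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pol[names(policies)] <- policies
  validate_policies(pol)
  structure(list(chart = chart, policies = pol), class = "run_config")
}

validate_policies <- function(pol) {
  if (!pol$fv_daily_rule %in% c("both", "either")) {
    stop("fv_daily_rule must be 'both' or 'either'", call. = FALSE)
  }
  if (!pol$sso_rule %in% c("all", "any")) {
    stop("sso_rule must be 'all' or 'any'", call. = FALSE)
  }
  if (!pol$missing %in% c("strict", "lenient")) {
    stop("missing must be 'strict' or 'lenient'", call. = FALSE)
  }
  if (pol$fruit_target < 0 || pol$veg_target < 0) {
    stop("serving targets must be >= 0", call. = FALSE)
  }
  invisible(pol)
}

#' Read a run configuration file
#'
#' Loads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration holding an
#' optional `limits` block (list of rows with `household_size`,
#' `salt_g_30d`, `sugar_g_30d`, `oil_ml_30d`) and an optional `policies`
#' block overriding the defaults. The file is parsed and validated before
#' any computation starts; a missing block falls back to the shipped
#' default. An example lives at
#' `system.file("extdata", "config_default.yaml", package = "hhstage")`.
#'
#' @param path path to the configuration file.
#' @return a `run_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be a .yaml/.yml or .json file, got: ", path,
         call. = FALSE)
  }
  chart <- if (!is.null(raw$limits)) {
    lim <- if (is.data.frame(raw$limits)) raw$limits else
      do.call(rbind, lapply(raw$limits, as.data.frame))
    need <- c("household_size", "salt_g_30d", "sugar_g_30d", "oil_ml_30d")
    miss <- setdiff(need, names(lim))
    if (length(miss) > 0L) {
      stop("limits block missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    limits_chart(lim$household_size, lim$salt_g_30d, lim$sugar_g_30d,
                 lim$oil_ml_30d)
  } else {
    default_limits_chart()
  }
  policies <- if (is.null(raw$policies)) list() else raw$policies
  default_config(chart = chart, policies = policies)
}
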