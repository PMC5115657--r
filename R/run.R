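# Table readers/writers and the programmatic entry points behind the CLI
# subcommands: stage, validate, alpha, simulate.

#' Read a raw responses table
#'
#' Reads `responses.csv` (comma-separated, header row, UTF-8) with every
#' column as character; optional columns may be empty. Validation happens
#' later, per algorithm version, in [validate_table()].
#'
#' @param path CSV file path.
#' @return data frame of character columns.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = TRUE, fileEncoding = "UTF-8")
  if (!"household_id" %in% names(df)) {
    stop("responses table must have a household_id column", call. = FALSE)
  }
  df
}

#' Read a paired stage-ratings table
#'
#' @param path CSV with columns `household_id`, `tool_stage`,
#'   `comparator_stage`.
#' @return data frame with canonical stage labels.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  need <- c("household_id", "tool_stage", "comparator_stage")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("ratings table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$tool_stage <- parse_stage(df$tool_stage)
  df$comparator_stage <- parse_stage(df$comparator_stage)
  df
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Stage a responses table end to end
#'
#' Reads (or takes) a raw responses table, validates it for the requested
#' algorithm version, stages every household, optionally writes
#' `stages.csv`, and logs per-stage and per-rule counts to standard error.
#' Under the lenient missing-data policy invalid rows are excluded (and
#' counted) instead of aborting the run.
#'
#' @param input path to `responses.csv` or a data frame.
#' @param output optional path for the stages CSV.
#' @param version algorithm version, 1, 2 or 3 (default 3).
#' @param config run configuration (see [default_config()],
#'   [read_config()]).
#' @return (invisibly) the stages data frame; the `excluded` attribute
#'   holds the rows rejected in lenient mode.
#' @export
run_stage <- function(input, output = NULL, version = 3,
                      config = default_config()) {
  df <- if (is.character(input)) read_responses(input) else input
  if (!is.data.frame(df) || nrow(df) == 0L) {
    stop("no households: the responses table is empty", call. = FALSE)
  }
  vt <- validate_table(df, version = version, mode = config$policies$missing)
  if (length(vt$records) == 0L) {
    stop("no households could be validated", call. = FALSE)
  }
  stages <- stage_households(vt$records, version = version, config = config)
  if (!is.null(output)) write_table(stages, output)
  message(sprintf("staged %d household(s) with algorithm version %d (%d excluded)",
                  nrow(stages), check_version(version), nrow(vt$excluded)))
  tab <- table(factor(stages$overall_stage, levels = STAGES))
  message("overall stages: ",
          paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                collapse = ", "))
  rules <- sort(table(c(stages$fv_rule, stages$sso_rule)), decreasing = TRUE)
  message("fired component rules: ",
          paste(sprintf("%s=%d", names(rules), as.integer(rules)),
                collapse = ", "))
  attr(stages, "excluded") <- vt$excluded
  invisible(stages)
}

#' Concurrent-validity report for paired stage ratings
#'
#' Computes percent agreement and the quadratic weighted kappa between tool
#' and comparator stages, with a seeded percentile-bootstrap confidence
#' interval and the asymptotic standard error as a secondary output.
#'
#' @param ratings path to `ratings.csv` or a data frame with columns
#'   `household_id`, `tool_stage`, `comparator_stage` (>= 2 rows).
#' @param output optional path for the JSON report.
#' @param n_boot bootstrap resamples (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed for the bootstrap stream.
#' @return (invisibly) the report list: `n`, `percent_agreement`, `kappa`,
#'   `ci`, `se_asymptotic`, `n_boot`, `level`, `seed`,
#'   `skipped_resamples`.
#' @export
run_validate <- function(ratings, output = NULL, n_boot = 2000, level = 0.95,
                         seed = 1) {
  df <- if (is.character(ratings)) read_ratings(ratings) else ratings
  if (!is.data.frame(df) || nrow(df) < 2L) {
    stop("need at least 2 rating pairs", call. = FALSE)
  }
  tab <- build_confusion(df$tool_stage, df$comparator_stage)
  ci <- bootstrap_kappa_ci(df$tool_stage, df$comparator_stage,
                           n_boot = n_boot, level = level, seed = seed)
  report <- list(
    n = nrow(df),
    percent_agreement = percent_agreement(tab),
    kappa = weighted_kappa(tab),
    ci = c(ci$lower, ci$upper),
    se_asymptotic = tryCatch(weighted_kappa_se(tab),
                             error = function(e) NA_real_),
    n_boot = n_boot, level = level, seed = seed,
    skipped_resamples = ci$skipped
  )
  if (!is.null(output)) {
    jsonlite::write_json(report, output, auto_unbox = TRUE, digits = NA)
  }
  message(sprintf("n=%d  agreement=%.1f%%  weighted kappa=%.3f  %d%% CI [%.3f, %.3f]",
                  report$n, report$percent_agreement, report$kappa,
                  round(100 * level), ci$lower, ci$upper))
  invisible(report)
}

#' Cronbach's alpha per reliability group
#'
#' Encodes the 17-item schema numerically (see [encode_items()]) and
#' computes Cronbach's alpha for each requested group: FV (8 items), SSO
#' (9 items) and OVERALL (15 items).
#'
#' @param responses path to `responses.csv` or a data frame.
#' @param stages path to `stages.csv` or a stage-results data frame from
#'   [run_stage()]/[stage_households()].
#' @param groups character vector among `"FV"`, `"SSO"`, `"OVERALL"`.
#' @param output optional path for the JSON report.
#' @param version algorithm version the responses were staged under.
#' @param config run configuration.
#' @return (invisibly) named list of per-group results, each with `alpha`,
#'   `k_items`, `n_households`, `excluded`.
#' @export
run_alpha <- function(responses, stages,
                      groups = c("FV", "SSO", "OVERALL"), output = NULL,
                      version = 3, config = default_config()) {
  groups <- match.arg(groups, several.ok = TRUE)
  df <- if (is.character(responses)) read_responses(responses) else responses
  st <- if (is.character(stages)) {
    utils::read.csv(stages, colClasses = "character", fileEncoding = "UTF-8")
  } else {
    stages
  }
  vt <- validate_table(df, version = version, mode = config$policies$missing)
  out <- lapply(groups, function(g) {
    m <- encode_items(vt$records, st, group = g, chart = config$chart,
                      sso_rule = config$policies$sso_rule)
    res <- cronbach_alpha(m, group = g)
    list(alpha = res$alpha, k_items = res$k_items,
         n_households = res$n_households,
         excluded = attr(m, "excluded"))
  })
  names(out) <- groups
  if (!is.null(output)) {
    jsonlite::write_json(out, output, auto_unbox = TRUE, digits = NA)
  }
  for (g in groups) {
    message(sprintf("alpha[%s] = %.3f  (%d items, %d households)", g,
                    out[[g]]$alpha, out[[g]]$k_items,
                    out[[g]]$n_households))
  }
  invisible(out)
}

#' Simulate a full validation dataset
#'
#' Generates synthetic households, stages them with the requested engine
#' version, draws comparator ratings from the truth, and (optionally)
#' writes the three tables: responses, paired ratings and truth.
#'
#' @param n number of households.
#' @param stage_probs per-component true-stage mix.
#' @param misclass comparator misclassification probability.
#' @param seed root seed.
#' @param component_dependence `"independent"` or `"identical"`.
#' @param version engine version used for the tool stages (default 3).
#' @param out_responses,out_ratings,out_truth optional CSV output paths.
#' @param config run configuration (chart is also used by the generator).
#' @return (invisibly) list with `responses`, `ratings`, `truth` data
#'   frames.
#' @export
run_simulate <- function(n, stage_probs = c(0.3, 0.4, 0.3), misclass = 0.1,
                         seed = 1, component_dependence = "independent",
                         version = 3, out_responses = NULL,
                         out_ratings = NULL, out_truth = NULL,
                         config = default_config()) {
  params <- simulation_params(n = n, stage_probs = stage_probs,
                              component_dependence = component_dependence,
                              misclass_prob = misclass, seed = seed)
  sim <- simulate_households(params, chart = config$chart)
  vt <- validate_table(sim$responses, version = version)
  tool <- stage_households(vt$records, version = version, config = config)
  comparator <- simulate_comparator(sim$truth$overall_true,
                                    d = params$misclass_prob, seed = seed)
  ratings <- data.frame(
    household_id = sim$truth$household_id,
    tool_stage = tool$overall_stage,
    comparator_stage = comparator
  )
  if (!is.null(out_responses)) write_table(sim$responses, out_responses)
  if (!is.null(out_ratings)) write_table(ratings, out_ratings)
  if (!is.null(out_truth)) write_table(sim$truth, out_truth)
  message(sprintf("simulated %d household(s), seed %d, misclass %.2f", n,
                  params$seed, params$misclass_prob))
  invisible(list(responses = sim$responses, ratings = ratings,
                 truth = sim$truth))
}
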