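#' Stage-of-change levels
#'
#' The instrument collapses the transtheoretical model's five stages to three
#' ordinal levels: pre-contemplation (`P`, no intention to change) <
#' intention (`I`, merged contemplation/preparation) < action (`A`, merged
#' action/maintenance).
#'
#' @format Character vector `c("P", "I", "A")` in rank order.
#' @export
STAGES <- c("P", "I", "A")

#' Parse stage labels
#'
#' Canonicalises stage labels to the single characters `P`, `I`, `A`.
#' Accepts any case, surrounding whitespace, and the full stage names
#' (`"pre-contemplation"`, `"intention"`, `"action"`).
#'
#' @param x character vector of stage labels.
#' @return character vector of canonical labels, same length as `x`.
#' @examples
#' parse_stage(c("p", " A ", "Intention"))
#' @export
parse_stage <- function(x) {
  up <- toupper(trimws(as.character(x)))
  full <- c(
    "PRE-CONTEMPLATION" = "P", "PRECONTEMPLATION" = "P",
    "INTENTION" = "I", "ACTION" = "A"
  )
  out <- ifelse(up %in% STAGES, up, unname(full[up]))
  bad <- is.na(out) | is.na(x)
  if (any(bad)) {
    stop("invalid stage label(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected P, I or A)", call. = FALSE)
  }
  out
}

#' Stage rank
#'
#' Integer order of a stage: `P` = 0 < `I` = 1 < `A` = 2.
#'
#' @param stage character vector of stage labels (any accepted spelling).
#' @return integer vector of ranks.
#' @examples
#' stage_rank(c("P", "I", "A"))
#' @export
stage_rank <- function(stage) {
  match(parse_stage(stage), STAGES) - 1L
}

#' Stage label from rank
#'
#' @param rank integer vector in `0:2`.
#' @return character vector of canonical stage labels.
#' @export
rank_stage <- function(rank) {
  rank <- as.integer(rank)
  if (any(is.na(rank) | rank < 0L | rank > 2L)) {
    stop("stage rank must be 0, 1 or 2", call. = FALSE)
  }
  STAGES[rank + 1L]
}

#' Ordered factor of stages
#'
#' @param x character vector of stage labels.
#' @return ordered factor with levels `P < I < A`.
#' @export
stage_factor <- function(x) {
  factor(parse_stage(x), levels = STAGES, ordered = TRUE)
}
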