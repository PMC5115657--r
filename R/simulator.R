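# Household simulator: seeded synthetic questionnaire responses with known
# true stages, a noisy ordinal comparator (a stand-in for the motivational
# interviewing rater), and closed-form oracles for the agreement statistics.

#' Simulation parameters
#'
#' @param n number of households (>= 1).
#' @param stage_probs probability triple `(pi_P, pi_I, pi_A)` for the true
#'   stage of each component; must sum to 1.
#' @param component_dependence `"independent"` (FV and SSO true stages drawn
#'   independently) or `"identical"` (both components share one draw, so
#'   the overall stage has marginal `stage_probs`).
#' @param misclass_prob probability `d` that the comparator departs from the
#'   true stage (always by one rank).
#' @param p_pattern probability triple over the three pre-contemplation
#'   response patterns (not willing / unsure timeframe / low confidence or
#'   cooperation); must sum to 1.
#' @param seed root integer seed; per-purpose substreams are derived from
#'   it so adding draws for one purpose never perturbs the others.
#' @return a validated `simulation_params` list.
#' @export
simulation_params <- function(n, stage_probs = c(0.3, 0.4, 0.3),
                              component_dependence = c("independent",
                                                       "identical"),
                              misclass_prob = 0.1,
                              p_pattern = c(1, 1, 1) / 3,
                              seed = 1) {
  component_dependence <- match.arg(component_dependence)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  check_probs <- function(p, what) {
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop(what, " must be 3 non-negative probabilities summing to 1",
           call. = FALSE)
    }
  }
  check_probs(stage_probs, "stage_probs")
  check_probs(p_pattern, "p_pattern")
  if (misclass_prob < 0 || misclass_prob > 1) {
    stop("misclass_prob must be in [0, 1]", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  structure(list(n = n, stage_probs = stage_probs,
                 component_dependence = component_dependence,
                 misclass_prob = misclass_prob, p_pattern = p_pattern,
                 seed = seed),
            class = "simulation_params")
}

# derived substream seed, kept inside 32-bit integer range
sub_seed <- function(seed, stream) {
  as.integer((abs(as.double(seed)) * 7919 + stream * 104729) %% 2147483587)
}

#' Simulate household questionnaire responses with known true stages
#'
#' Draws a true stage per component from `stage_probs` and constructs
#' questionnaire responses that the final (Version 3) staging engine maps
#' back to that true stage exactly: action households consume FV daily and
#' keep all SSO components at or below the limits; intention households have
#' inadequate consumption but are willing to change immediately with
#' confidence 5 and cooperation 4-5; pre-contemplation households have
#' inadequate consumption and one of three disqualifying response patterns
#' drawn from `p_pattern`. Serving counts are generated consistently with
#' the daily indicators, so Version 2 stages the records identically.
#' Household sizes are uniform over the chart's covered range. Deterministic
#' given the seed.
#'
#' @param params a [simulation_params()] object.
#' @param chart limits chart used for the SSO quantities (and for staging).
#' @return list with `responses` (raw responses data frame in the
#'   `responses.csv` column layout) and `truth` (data frame of
#'   `household_id`, `fv_true`, `sso_true`, `overall_true`).
#' @examples
#' sim <- simulate_households(simulation_params(n = 5, seed = 42))
#' sim$truth
#' @export
simulate_households <- function(params, chart = default_limits_chart()) {
  stopifnot(inherits(params, "simulation_params"))
  n <- params$n
  seed <- params$seed

  sizes <- with_seed(sub_seed(seed, 1L),
                     sample(chart$household_size, n, replace = TRUE))
  fv_true <- with_seed(sub_seed(seed, 2L),
                       sample(STAGES, n, replace = TRUE,
                              prob = params$stage_probs))
  sso_true <- if (params$component_dependence == "identical") {
    fv_true
  } else {
    with_seed(sub_seed(seed, 3L),
              sample(STAGES, n, replace = TRUE, prob = params$stage_probs))
  }

  # FV consumption: which daily indicator(s) are "no" for non-action
  # households, with serving counts consistent with the indicators
  fvc <- with_seed(sub_seed(seed, 4L), list(
    miss = sample(3L, n, replace = TRUE),       # 1 fruit, 2 veg, 3 both
    fs_hi = sample(2:5, n, replace = TRUE), fs_lo = sample(0:1, n, TRUE),
    vs_hi = sample(3:6, n, replace = TRUE), vs_lo = sample(0:2, n, TRUE)
  ))
  fruit_daily <- fv_true == "A" | !(fvc$miss %in% c(1L, 3L))
  veg_daily <- fv_true == "A" | !(fvc$miss %in% c(2L, 3L))
  fruit_serv <- ifelse(fruit_daily, fvc$fs_hi, fvc$fs_lo)
  veg_serv <- ifelse(veg_daily, fvc$vs_hi, fvc$vs_lo)

  staging_block <- function(true, stream) {
    draws <- with_seed(sub_seed(seed, stream), list(
      pattern = sample(3L, n, replace = TRUE, prob = params$p_pattern),
      low_which = sample(2L, n, replace = TRUE),
      conf_any = sample(5L, n, replace = TRUE),
      coop_any = sample(5L, n, replace = TRUE),
      conf_low = sample(1:4, n, replace = TRUE),
      coop_hi = sample(4:5, n, replace = TRUE),
      coop_low = sample(1:3, n, replace = TRUE),
      tf_any = sample(c("immediate", "unsure"), n, replace = TRUE)
    ))
    willing <- rep(TRUE, n)
    timeframe <- rep("immediate", n)
    confidence <- rep(5L, n)
    cooperation <- draws$coop_hi
    isP <- true == "P"
    p1 <- isP & draws$pattern == 1L   # not willing
    p2 <- isP & draws$pattern == 2L   # unsure timeframe
    p3 <- isP & draws$pattern == 3L   # low confidence or cooperation
    willing[p1] <- FALSE
    timeframe[p1] <- draws$tf_any[p1]
    confidence[p1] <- draws$conf_any[p1]
    cooperation[p1] <- draws$coop_any[p1]
    timeframe[p2] <- "unsure"
    confidence[p2] <- draws$conf_any[p2]
    cooperation[p2] <- draws$coop_any[p2]
    lowc <- p3 & draws$low_which == 1L
    confidence[lowc] <- draws$conf_low[lowc]
    cooperation[lowc] <- draws$coop_hi[lowc]
    cooperation[p3 & !lowc] <- draws$coop_low[p3 & !lowc]
    isA <- true == "A"                # staging answers free under action
    timeframe[isA] <- draws$tf_any[isA]
    confidence[isA] <- draws$conf_any[isA]
    cooperation[isA] <- draws$coop_any[isA]
    list(willing = willing, timeframe = timeframe,
         confidence = confidence, cooperation = cooperation)
  }
  fv_sr <- staging_block(fv_true, 5L)
  sso_sr <- staging_block(sso_true, 6L)

  # SSO quantities: action households at or below every limit; others have
  # exactly one randomly chosen component over its limit
  lim <- as.matrix(lookup_limits(chart, sizes))
  ssoq <- with_seed(sub_seed(seed, 7L), list(
    frac_ok = matrix(stats::runif(3L * n, 0.4, 1.0), n, 3L),
    over_comp = sample(3L, n, replace = TRUE),
    frac_over = stats::runif(n, 1.05, 1.6)
  ))
  qty <- ssoq$frac_ok * lim
  over <- sso_true != "A"
  qty[cbind(which(over), ssoq$over_comp[over])] <-
    (ssoq$frac_over * lim[cbind(seq_len(n), ssoq$over_comp)])[over]
  qty <- round(qty, 1)

  yn <- function(x) ifelse(x, "yes", "no")
  responses <- data.frame(
    household_id = sprintf("HH%05d", seq_len(n)),
    household_size = as.character(sizes),
    fruit_daily = yn(fruit_daily),
    vegetable_daily = yn(veg_daily),
    fruit_servings = as.character(fruit_serv),
    vegetable_servings = as.character(veg_serv),
    salt_g_30d = as.character(qty[, 1L]),
    sugar_g_30d = as.character(qty[, 2L]),
    oil_ml_30d = as.character(qty[, 3L]),
    fv_willing = yn(fv_sr$willing),
    fv_timeframe = fv_sr$timeframe,
    fv_confidence = as.character(fv_sr$confidence),
    fv_cooperation = as.character(fv_sr$cooperation),
    sso_willing = yn(sso_sr$willing),
    sso_timeframe = sso_sr$timeframe,
    sso_confidence = as.character(sso_sr$confidence),
    sso_cooperation = as.character(sso_sr$cooperation),
    interest_recommendations = "",
    fv_following = "",
    sso_following = ""
  )
  truth <- data.frame(
    household_id = responses$household_id,
    fv_true = fv_true,
    sso_true = sso_true,
    overall_true = rank_stage(pmin(stage_rank(fv_true),
                                   stage_rank(sso_true)))
  )
  list(responses = responses, truth = truth)
}

#' Simulate comparator stage ratings
#'
#' Models the comparator (a motivational-interviewing-style rater) as a
#' noisy ordinal channel: with probability `1 - d` it returns the true
#' stage; with probability `d` it moves exactly one rank (P to I, A to I;
#' I to P or A with probability `d/2` each). It never jumps two ranks.
#'
#' @param true_stage character vector of true stage labels.
#' @param d misclassification probability in `[0, 1]`.
#' @param seed integer seed for the comparator stream.
#' @return character vector of comparator stage labels.
#' @examples
#' simulate_comparator(c("P", "I", "A"), d = 0, seed = 1)
#' @export
simulate_comparator <- function(true_stage, d, seed = 1) {
  if (d < 0 || d > 1) stop("d must be in [0, 1]", call. = FALSE)
  truth <- parse_stage(true_stage)
  n <- length(truth)
  with_seed(sub_seed(seed, 8L), {
    move <- stats::runif(n) < d
    dir_up <- stats::runif(n) < 0.5
    out <- truth
    out[move & truth %in% c("P", "A")] <- "I"
    out[move & truth == "I"] <- ifelse(dir_up[move & truth == "I"], "A", "P")
    out
  })
}

#' Closed-form expected weighted kappa under the comparator model
#'
#' Oracle for the agreement statistics: the quadratic weighted kappa of the
#' joint distribution implied by an overall-stage marginal and the
#' off-by-one comparator channel, computed on probabilities instead of
#' counts. Observed weighted disagreement is `d/4` for any marginal (every
#' comparator error moves one rank, weight 1/4); the expected disagreement
#' comes from the marginals.
#'
#' @param stage_probs overall-stage marginal `(p_P, p_I, p_A)`.
#' @param d comparator misclassification probability.
#' @return numeric scalar kappa.
#' @examples
#' expected_weighted_kappa(c(0.3, 0.4, 0.3), d = 0.10)  # 54/59
#' @export
expected_weighted_kappa <- function(stage_probs, d) {
  if (length(stage_probs) != 3L || any(stage_probs < 0) ||
      abs(sum(stage_probs) - 1) > 1e-12) {
    stop("stage_probs must be 3 probabilities summing to 1", call. = FALSE)
  }
  if (d < 0 || d > 1) stop("d must be in [0, 1]", call. = FALSE)
  p <- stage_probs
  channel <- rbind(
    c(1 - d, d, 0),
    c(d / 2, 1 - d, d / 2),
    c(0, d, 1 - d)
  )
  joint <- diag(p) %*% channel
  q <- colSums(joint)
  w <- quadratic_weights(3L)
  po <- sum(w * joint)
  pe <- sum(w * outer(p, q))
  if (pe <= .Machine$double.eps) {
    if (po <= .Machine$double.eps) return(1)
    stop("degenerate marginal: expected disagreement is zero", call. = FALSE)
  }
  1 - po / pe
}

#' Overall-stage marginal implied by the component stage mix
#'
#' With independent components and rank-minimum combination,
#' `P(overall = A) = pi_A^2` and `P(overall = P) = 1 - (1 - pi_P)^2`; with
#' identical components the overall marginal equals the component marginal.
#'
#' @param stage_probs component stage marginal `(pi_P, pi_I, pi_A)`.
#' @param component_dependence `"independent"` or `"identical"`.
#' @return named probability triple over `P`, `I`, `A`.
#' @examples
#' overall_stage_probs(c(0.3, 0.4, 0.3))
#' @export
overall_stage_probs <- function(stage_probs,
                                component_dependence = c("independent",
                                                         "identical")) {
  component_dependence <- match.arg(component_dependence)
  p <- stage_probs
  out <- if (component_dependence == "identical") {
    c(p[1L], p[2L], p[3L])
  } else {
    pP <- 1 - (1 - p[1L])^2
    pA <- p[3L]^2
    c(pP, 1 - pP - pA, pA)
  }
  stats::setNames(out, STAGES)
}

#' Simulate parallel item scores for the alpha oracle
#'
#' Generates `k` parallel items: each is `sqrt(r)` times a shared latent
#' trait plus `sqrt(1 - r)` times independent noise (all unit variance), so
#' every item pair has correlation `r` and the population Cronbach's alpha
#' equals the Spearman-Brown form `k * r / (1 + (k - 1) * r)`.
#'
#' @param n number of households (rows).
#' @param k number of items (>= 2).
#' @param r target pairwise correlation, `0 <= r < 1`.
#' @param seed integer seed.
#' @return numeric `n x k` matrix with columns `item01`, `item02`, ...
#' @examples
#' cronbach_alpha(simulate_item_scores(2000, 8, 0.4, seed = 1))
#' @export
simulate_item_scores <- function(n, k, r, seed = 1) {
  if (r < 0 || r >= 1) stop("r must be in [0, 1)", call. = FALSE)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  with_seed(sub_seed(seed, 9L), {
    latent <- stats::rnorm(n)
    noise <- matrix(stats::rnorm(n * k), n, k)
    m <- sqrt(r) * latent + sqrt(1 - r) * noise
    colnames(m) <- sprintf("item%02d", seq_len(k))
    m
  })
}
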