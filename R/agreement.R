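# Concurrent-validity and reliability statistics: percent agreement,
# quadratic weighted kappa (with seeded percentile-bootstrap CI and the
# large-sample SE as a secondary output), and Cronbach's alpha.

#' Build a 3x3 stage confusion table
#'
#' Cross-tabulates paired stage ratings (tool vs comparator) over the three
#' ordinal stages, in rank order P, I, A. All nine cells are present (zeros
#' allowed).
#'
#' @param tool,comparator character vectors of stage labels, same length.
#' @return a `confusion_table`: 3x3 integer matrix, tool stages in rows.
#' @examples
#' build_confusion(c("P", "I", "A"), c("P", "I", "A"))
#' @export
build_confusion <- function(tool, comparator) {
  if (length(tool) == 0L) stop("no rating pairs", call. = FALSE)
  if (length(tool) != length(comparator)) {
    stop("tool and comparator ratings differ in length", call. = FALSE)
  }
  tab <- table(
    tool = factor(parse_stage(tool), levels = STAGES),
    comparator = factor(parse_stage(comparator), levels = STAGES)
  )
  out <- matrix(as.integer(tab), 3L, 3L,
                dimnames = list(tool = STAGES, comparator = STAGES))
  class(out) <- c("confusion_table", class(out))
  out
}

as_count_matrix <- function(x) {
  m <- unclass(x)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("expected a square confusion matrix", call. = FALSE)
  }
  if (any(m < 0) || sum(m) <= 0) {
    stop("confusion table must have non-negative counts and n > 0",
         call. = FALSE)
  }
  m
}

#' Percent agreement
#'
#' Share of pairs on the diagonal, as a percentage in `[0, 100]`.
#'
#' @param table a [build_confusion()] table (or any square count matrix).
#' @return numeric scalar.
#' @examples
#' percent_agreement(build_confusion(c("P", "I"), c("P", "A")))
#' @export
percent_agreement <- function(table) {
  m <- as_count_matrix(table)
  100 * sum(diag(m)) / sum(m)
}

#' Quadratic disagreement weights
#'
#' Disagreement weights for weighted kappa over `k` ordinal categories:
#' `w_ij = (i - j)^2 / (k - 1)^2`, zero on the diagonal, 1 at the extreme
#' pair. The quadratic form penalises distant disagreements more and is the
#' usual choice for ordinal stage ratings.
#'
#' @param k number of categories (>= 2).
#' @return `k x k` symmetric numeric matrix.
#' @examples
#' quadratic_weights(3)
#' @export
quadratic_weights <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be >= 2", call. = FALSE)
  i <- seq_len(k)
  outer(i, i, function(a, b) (a - b)^2) / (k - 1)^2
}

#' Quadratic weighted kappa
#'
#' Chance-corrected agreement for ordinal ratings,
#' `kappa_w = 1 - (sum w_ij O_ij / n) / (sum w_ij p_i q_j)`, with `w` the
#' disagreement weights (quadratic by default), and `p`, `q` the tool and
#' comparator marginal proportions. Perfect agreement gives exactly 1; a
#' table equal to the outer product of its marginals gives 0.
#'
#' A table with zero expected weighted disagreement is degenerate: when the
#' observed disagreement is also zero (all mass on one diagonal cell) the
#' perfect-agreement value 1 is returned; otherwise the statistic is
#' undefined and an error is raised.
#'
#' @param table a [build_confusion()] table or square count matrix.
#' @param weights optional disagreement-weight matrix; defaults to
#'   [quadratic_weights()] of the table's dimension.
#' @return numeric scalar in `[-1, 1]`.
#' @examples
#' tab <- build_confusion(rep(c("P", "I", "A"), 10), rep(c("P", "I", "A"), 10))
#' weighted_kappa(tab)
#' @export
weighted_kappa <- function(table, weights = NULL) {
  m <- as_count_matrix(table)
  k <- nrow(m)
  w <- if (is.null(weights)) quadratic_weights(k) else weights
  stopifnot(identical(dim(w), dim(m)))
  n <- sum(m)
  p <- rowSums(m) / n
  q <- colSums(m) / n
  po <- sum(w * m) / n          # observed weighted disagreement
  pe <- sum(w * outer(p, q))    # expected weighted disagreement
  if (pe <= .Machine$double.eps) {
    if (po <= .Machine$double.eps) return(1)
    stop("weighted kappa undefined: zero expected disagreement with ",
         "non-zero observed disagreement", call. = FALSE)
  }
  1 - po / pe
}

#' Large-sample standard error of weighted kappa
#'
#' Asymptotic (Fleiss-Cohen-Everitt) standard error of the weighted kappa
#' estimate, offered as a secondary output alongside the bootstrap interval.
#'
#' @inheritParams weighted_kappa
#' @return numeric scalar standard error.
#' @export
weighted_kappa_se <- function(table, weights = NULL) {
  m <- as_count_matrix(table)
  k <- nrow(m)
  w <- if (is.null(weights)) quadratic_weights(k) else weights
  v <- 1 - w                    # agreement-weight parameterisation
  n <- sum(m)
  pm <- m / n
  p <- rowSums(pm)
  q <- colSums(pm)
  po <- sum(v * pm)
  pe <- sum(v * outer(p, q))
  if (1 - pe <= .Machine$double.eps) {
    stop("asymptotic SE undefined for degenerate marginals", call. = FALSE)
  }
  vi <- as.vector(v %*% q)      # row means of agreement weights
  vj <- as.vector(p %*% v)      # column means
  term <- outer(vi, vj, `+`)
  s <- sum(pm * (v * (1 - pe) - term * (1 - po))^2)
  num <- s - (po * pe - 2 * pe + po)^2
  sqrt(max(num, 0) / (n * (1 - pe)^4))
}

# evaluate code with a locally-set RNG seed, restoring global state after
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  force(code)
}

#' Percentile bootstrap confidence interval for weighted kappa
#'
#' Resamples rating pairs (households) with replacement and returns the
#' percentile interval of the quadratic weighted kappa. Resamples whose
#' confusion table has a degenerate marginal (fewer than two occupied
#' categories on either axis) without being in perfect agreement are
#' skipped and counted. Deterministic given `seed`.
#'
#' @param tool,comparator paired stage labels (>= 2 pairs).
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed for the resampling stream.
#' @return list with `lower`, `upper`, `level`, `n_boot`, `skipped`, `seed`.
#' @examples
#' tool <- rep(c("P", "I", "A"), c(5, 6, 4))
#' comp <- tool; comp[1] <- "I"
#' bootstrap_kappa_ci(tool, comp, n_boot = 200, seed = 7)
#' @export
bootstrap_kappa_ci <- function(tool, comparator, n_boot = 2000, level = 0.95,
                               seed = 1) {
  tool <- parse_stage(tool)
  comparator <- parse_stage(comparator)
  n <- length(tool)
  if (n < 2L || length(comparator) != n) {
    stop("need at least 2 aligned rating pairs", call. = FALSE)
  }
  kappas <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tab <- build_confusion(tool[idx], comparator[idx])
      m <- unclass(tab)
      degenerate <- sum(rowSums(m) > 0) < 2L || sum(colSums(m) > 0) < 2L
      perfect <- sum(diag(m)) == sum(m)
      if (degenerate && !perfect) return(NA_real_)
      tryCatch(weighted_kappa(tab), error = function(e) NA_real_)
    }, numeric(1L))
  })
  skipped <- sum(is.na(kappas))
  if (skipped == n_boot) {
    stop("all bootstrap resamples were degenerate", call. = FALSE)
  }
  alpha <- 1 - level
  qs <- stats::quantile(kappas, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                        names = FALSE)
  list(lower = qs[1L], upper = qs[2L], level = level, n_boot = n_boot,
       skipped = skipped, seed = seed)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability,
#' `alpha = k/(k-1) * (1 - sum(s_i^2) / s_X^2)`, with `s_i^2` the item
#' sample variances and `s_X^2` the variance of the row (total) scores,
#' both on the `n - 1` denominator. Items with zero variance are rejected
#' by name, as is a zero total-score variance.
#'
#' @param x numeric matrix or data frame, households in rows, items in
#'   columns (an [encode_items()] matrix fits directly).
#' @param group optional group label (`"FV"`, `"SSO"`, `"OVERALL"`) carried
#'   into the result; taken from the matrix's `group` attribute if present.
#' @return an `alpha_result`: list with `alpha`, `k_items`, `n_households`,
#'   `group`.
#' @examples
#' m <- simulate_item_scores(n = 500, k = 8, r = 0.4, seed = 1)
#' cronbach_alpha(m)$alpha
#' @export
cronbach_alpha <- function(x, group = NULL) {
  if (is.null(group)) group <- attr(x, "group")
  m <- as.matrix(as.data.frame(unclass(x)))
  storage.mode(m) <- "double"
  k <- ncol(m)
  n <- nrow(m)
  if (k < 2L) stop("Cronbach's alpha needs at least 2 items", call. = FALSE)
  if (n < 2L) stop("Cronbach's alpha needs at least 2 households",
                   call. = FALSE)
  if (anyNA(m)) stop("item matrix contains missing values", call. = FALSE)
  item_vars <- apply(m, 2L, stats::var)
  const <- item_vars <= 0
  if (any(const)) {
    stop("zero-variance item(s): ",
         paste(colnames(m)[const], collapse = ", "), call. = FALSE)
  }
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) stop("zero total-score variance", call. = FALSE)
  alpha <- k / (k - 1) * (1 - sum(item_vars) / total_var)
  structure(list(alpha = alpha, k_items = k, n_households = n,
                 group = if (is.null(group)) NA_character_ else group),
            class = "alpha_result")
}

#' @export
print.alpha_result <- function(x, ...) {
  cat(sprintf("Cronbach's alpha: %.3f  (%s, %d items, %d households)\n",
              x$alpha, ifelse(is.na(x$group), "ungrouped", x$group),
              x$k_items, x$n_households))
  invisible(x)
}
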