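check_groups <- function(groups, min_per_group = 2L) {
  if (!is.list(groups) || length(groups) < 2)
    stop("`groups` must be a list of >= 2 numeric vectors", call. = FALSE)
  if (any(vapply(groups, length, 1L) < min_per_group))
    stop("every group needs >= ", min_per_group, " values", call. = FALSE)
  if (any(vapply(groups, anyNA, TRUE)))
    stop("missing values are not allowed", call. = FALSE)
  invisible(groups)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects F test with `(k - 1, N - k)` degrees of freedom
#' (equal-variance form, as in `stats::oneway.test(var.equal = TRUE)`).
#' When the within-group variance is exactly zero the F ratio degenerates:
#' equal means give `F = 0, p = 1`; unequal means give `F = Inf, p = 0`.
#'
#' @param groups List of numeric vectors, one per group (each length >= 2).
#' @return List: `statistic` (F), `p.value`, `df` (numerator, denominator).
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  k <- length(groups)
  n <- vapply(groups, length, 1L)
  N <- sum(n)
  gm <- vapply(groups, mean, 1)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df <- c(k - 1L, N - k)
  if (ssw == 0) {
    ssb <- sum(n * (gm - sum(n * gm) / N)^2)
    if (ssb == 0) return(list(statistic = 0, p.value = 1, df = df))
    return(list(statistic = Inf, p.value = 0, df = df))
  }
  ht <- stats::oneway.test(value ~ g,
                           data = data.frame(value = unlist(groups),
                                             g = factor(rep(seq_len(k), n))),
                           var.equal = TRUE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value, df = df)
}

pooled_t_test <- function(x, y, df = NULL, s2 = NULL) {
  # equal-variance two-sample t; df/s2 may be supplied (e.g. pooled over
  # all groups of a design) instead of the pairwise pooled variance
  nx <- length(x); ny <- length(y)
  if (is.null(s2)) {
    df <- nx + ny - 2L
    s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  }
  se <- sqrt(s2 * (1 / nx + 1 / ny))
  est <- mean(x) - mean(y)
  if (se == 0) {
    t <- if (est == 0) 0 else sign(est) * Inf
  } else t <- est / se
  list(estimate = est, t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Dunnett comparisons against a control group
#'
#' Two-sided comparisons of every treatment group against the designated
#' control, using t statistics built on the variance pooled over all
#' groups (`N - k` degrees of freedom). The family-wise adjusted p value of
#' each comparison is `P(max_i |T_i| >= |t_obs|)` under the joint null,
#' estimated by seeded Monte-Carlo simulation of the correlated t vector
#' (`n_mc` draws of the group means and of the pooled variance). The
#' adjusted p is floored at the unadjusted single-comparison p, which it
#' dominates analytically.
#'
#' @param groups List of numeric vectors (each length >= 2).
#' @param control Index of the control group within `groups`.
#' @param n_mc Monte-Carlo draws (>= 1000; the adjusted-p standard error is
#'   about `sqrt(p (1 - p) / n_mc)`).
#' @param seed Seed for the Monte-Carlo draws.
#' @return Data frame with one row per non-control group: `group`
#'   (index), `estimate` (mean difference vs. control), `t`, `df`, `p_raw`
#'   (unadjusted), `p_adj` (Dunnett-adjusted).
#' @export
dunnett_vs_control <- function(groups, control = 1L, n_mc = 100000L, seed = 1L) {
  check_groups(groups)
  if (n_mc < 1000)
    stop("n_mc must be >= 1000: smaller Monte-Carlo samples give too coarse an adjustment",
         call. = FALSE)
  k <- length(groups)
  if (control < 1 || control > k) stop("invalid control index", call. = FALSE)
  n <- vapply(groups, length, 1L)
  N <- sum(n)
  df <- N - k
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1)) / df
  idx <- setdiff(seq_len(k), control)

  obs <- lapply(idx, function(i)
    pooled_t_test(groups[[i]], groups[[control]], df = df, s2 = s2))
  tobs <- vapply(obs, `[[`, 1, "t")

  maxT <- withr::with_seed(as.integer(seed), {
    zbar <- matrix(rnorm(n_mc * k), n_mc, k) %*% diag(1 / sqrt(n), k)
    sp2 <- rchisq(n_mc, df) / df
    do.call(pmax, lapply(idx, function(i) {
      abs(zbar[, i] - zbar[, control]) /
        sqrt(sp2 * (1 / n[i] + 1 / n[control]))
    }))
  })
  p_adj <- vapply(tobs, function(t) {
    (1 + sum(maxT >= abs(t))) / (n_mc + 1)
  }, 1)
  p_raw <- vapply(obs, `[[`, 1, "p")
  data.frame(group = idx,
             estimate = vapply(obs, `[[`, 1, "estimate"),
             t = tobs, df = df, p_raw = p_raw,
             p_adj = pmax(pmin(p_adj, 1), p_raw))
}

#' Bonferroni-adjusted pooled t tests for selected group pairs
#'
#' Equal-variance two-sided t test for each requested pair, with the
#' adjusted p equal to `min(1, m * p)` where `m` is the number of selected
#' pairs.
#'
#' @param groups List of numeric vectors (each length >= 2).
#' @param pairs List of length-2 integer vectors of group indices.
#' @return Data frame: `i`, `j`, `estimate`, `t`, `df`, `p_raw`, `p_adj`.
#' @export
bonferroni_pairs <- function(groups, pairs) {
  check_groups(groups)
  if (!length(pairs)) stop("no pairs requested", call. = FALSE)
  rows <- lapply(pairs, function(p) {
    if (length(p) != 2 || any(p < 1) || any(p > length(groups)) || p[1] == p[2])
      stop("each pair must be two distinct valid group indices", call. = FALSE)
    ht <- pooled_t_test(groups[[p[1]]], groups[[p[2]]])
    data.frame(i = p[1], j = p[2], estimate = ht$estimate, t = ht$t,
               df = ht$df, p_raw = ht$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "bonferroni")
  out
}

#' Empirical ROC curve and area under it
#'
#' Sweeps all distinct score values as thresholds and records
#' (sensitivity, 1 - specificity) at each, always including the trivial
#' operating points (0, 0) and (1, 1). The area under the curve is computed
#' by the trapezoidal rule, which equals the Mann-Whitney probability that
#' a random positive scores above a random negative, with ties credited
#' 1/2.
#'
#' @param positive_scores,negative_scores Numeric score vectors (each
#'   non-empty).
#' @param direction `"greater_is_positive"` if larger scores indicate the
#'   positive class, `"lesser_is_positive"` otherwise.
#' @return Object of class `roc_result`: `operating_points` (data.frame
#'   with `sensitivity`, `one_minus_specificity`), `auc`, `band` (see
#'   [classify_auc()]), `direction`.
#' @export
roc_curve <- function(positive_scores, negative_scores,
                      direction = c("greater_is_positive", "lesser_is_positive")) {
  direction <- match.arg(direction)
  if (!length(positive_scores) || !length(negative_scores))
    stop("both classes need at least one score", call. = FALSE)
  if (anyNA(positive_scores) || anyNA(negative_scores))
    stop("missing scores are not allowed", call. = FALSE)
  pos <- as.numeric(positive_scores)
  neg <- as.numeric(negative_scores)
  if (direction == "lesser_is_positive") { pos <- -pos; neg <- -neg }
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(pos >= t), 1)
  fpr <- vapply(thr, function(t) mean(neg >= t), 1)
  sens <- c(0, sens); fpr <- c(0, fpr)      # threshold above every score
  n <- length(sens)
  auc <- sum(diff(fpr) * (sens[-1] + sens[-n]) / 2)
  structure(
    list(operating_points = data.frame(sensitivity = sens,
                                       one_minus_specificity = fpr),
         auc = auc, band = classify_auc(auc), direction = direction),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%s)\n", x$auc, as.character(x$band)))
  invisible(x)
}

#' Accuracy band of an area under the ROC curve
#'
#' Left-closed, right-open intervals: below 0.6 the classifier has no
#' practical value; `[0.6, 0.7)` poor, `[0.7, 0.8)` fair, `[0.8, 0.9)`
#' good, and 0.9 or above excellent.
#'
#' @param auc Numeric vector of AUC values in `[0, 1]`.
#' @return Ordered factor with levels
#'   `no_value < poor < fair < good < excellent`.
#' @export
classify_auc <- function(auc) {
  if (anyNA(auc) || any(auc < 0) || any(auc > 1))
    stop("auc must lie in [0, 1]", call. = FALSE)
  lv <- c("no_value", "poor", "fair", "good", "excellent")
  cut(auc, breaks = c(-Inf, 0.6, 0.7, 0.8, 0.9, Inf), labels = lv,
      right = FALSE, ordered_result = TRUE)
}
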