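## Standardized-difference balance diagnostics: crude, hdPS-quintile
## stratified, and regression-weighted forms, for continuous and binary
## covariates, plus a report over a whole covariate matrix before and after
## matching.

#' Standardized difference for a continuous covariate
#'
#' d = (mean1 - mean2) / sqrt((var1 + var2) / 2).
#'
#' @param mean1,mean2 group sample means
#' @param var1,var2 group sample variances (>= 0, not both 0 unless the
#'   means agree)
#' @return d (0 when both variances are 0 and the means agree; signed
#'   infinite with a warning when both are 0 and the means differ)
#' @export
#' @examples
#' smd_continuous(2, 1, 1, 3)
smd_continuous <- function(mean1, mean2, var1, var2) {
  if (var1 < 0 || var2 < 0) stop_config("variances must be >= 0")
  if (var1 == 0 && var2 == 0) {
    if (mean1 == mean2) return(0)
    warning("degenerate covariate: zero variance in both groups with ",
            "different means; infinite imbalance")
    return(sign(mean1 - mean2) * Inf)
  }
  (mean1 - mean2) / sqrt((var1 + var2) / 2)
}

#' Standardized difference for a binary covariate
#'
#' d = (p1 - p2) / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2).
#'
#' @param p1,p2 group proportions in \[0, 1\]
#' @return d (conventions for degenerate proportions as in
#'   [smd_continuous()])
#' @export
#' @examples
#' smd_binary(0.3, 0.2)
smd_binary <- function(p1, p2) {
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1))
    stop_config("proportions must be within [0, 1]")
  smd_continuous(p1, p2, p1 * (1 - p1), p2 * (1 - p2))
}

is_binary <- function(x) all(x %in% c(0, 1, NA))

## crude d for a vector given group-1 indicator
smd_crude <- function(values, g1) {
  if (is_binary(values)) {
    smd_binary(mean(values[g1]), mean(values[!g1]))
  } else {
    smd_continuous(mean(values[g1]), mean(values[!g1]),
                   var(values[g1]), var(values[!g1]))
  }
}

#' Score-quintile stratified standardized difference
#'
#' Cuts the cohort at the pooled score quintiles (boundary patients go to
#' the lower stratum), computes the crude d within each stratum and
#' combines the strata by size-weighted average. Strata with an empty arm
#' are skipped with a warning and the weights renormalized. With a single
#' effective stratum (all scores equal) the result equals the crude d.
#'
#' @param values covariate vector
#' @param groups logical vector (TRUE = group 1)
#' @param scores fitted propensity scores
#' @param n_strata number of score strata (default 5)
#' @return weighted-average standardized difference
#' @export
smd_stratified <- function(values, groups, scores, n_strata = 5L) {
  g1 <- as.logical(groups)
  br <- unique(quantile(scores, seq(0, 1, length.out = n_strata + 1L),
                        names = FALSE))
  if (length(br) < 3L) return(smd_crude(values, g1))
  st <- cut(scores, breaks = br, include.lowest = TRUE, right = TRUE,
            labels = FALSE)
  ds <- numeric(0); ws <- numeric(0)
  for (s in sort(unique(st))) {
    in_s <- st == s
    if (!any(in_s & g1) || !any(in_s & !g1)) {
      warning("score stratum ", s, " has an empty arm; skipped")
      next
    }
    ds <- c(ds, smd_crude(values[in_s], g1[in_s]))
    ws <- c(ws, sum(in_s))
  }
  if (!length(ds)) stop_config("no stratum with both arms present")
  sum(ds * ws / sum(ws))
}

#' Regression-weighted standardized difference
#'
#' Fits covariate ~ score + group + score x group (linear model for a
#' continuous covariate, logistic for a binary one), predicts each
#' patient's covariate under group 1 and under group 2 at the pooled score
#' distribution, and applies the crude formula to the two sets of
#' predictions (for a continuous covariate the denominator keeps the
#' observed group variances).
#'
#' @inheritParams smd_stratified
#' @return standardized difference from model predictions
#' @export
smd_weighted <- function(values, groups, scores) {
  g1 <- as.logical(groups)
  dat <- data.frame(y = values, s = scores, g = as.numeric(g1))
  binary <- is_binary(values)
  if (binary && length(unique(values)) == 1L)
    stop_config("binary covariate is constant; weighted d undefined")
  fit <- if (binary) {
    glm(y ~ s * g, family = binomial(), data = dat)
  } else {
    lm(y ~ s * g, data = dat)
  }
  if (binary && !fit$converged)
    stop_config("weighted-difference regression did not converge")
  p1 <- predict(fit, newdata = transform(dat, g = 1), type = "response")
  p2 <- predict(fit, newdata = transform(dat, g = 0), type = "response")
  if (binary) {
    smd_binary(mean(p1), mean(p2))
  } else {
    smd_continuous(mean(p1), mean(p2), var(values[g1]), var(values[!g1]))
  }
}

#' Balance report over a covariate matrix
#'
#' Computes the crude standardized difference for every column of `X`
#' between the two arms, and, when a `matched_cohort` is supplied, the same
#' quantity restricted to the matched patients. Stratified and weighted
#' differences are added for the requested columns when scores are given.
#'
#' @param X numeric covariate matrix with named columns; rownames are
#'   patient ids
#' @param treated logical vector (rows of X)
#' @param matched optional `matched_cohort`
#' @param scores optional fitted scores (for stratified/weighted d)
#' @param detailed_columns columns for which stratified and weighted d are
#'   computed (default none; these require one regression per covariate)
#' @return list with `table` (data.table: covariate, type, d_crude,
#'   d_matched, d_stratified, d_weighted, and the same in percent) and
#'   `summary` (max |d| and counts above 0.02 / 0.10, crude and matched)
#' @export
balance_report <- function(X, treated, matched = NULL, scores = NULL,
                           detailed_columns = character()) {
  g1 <- as.logical(treated)
  ids <- rownames(X)
  cols <- colnames(X)
  d_crude <- vapply(cols, function(j)
    suppressWarnings(smd_crude(X[, j], g1)), numeric(1))

  d_matched <- rep(NA_real_, length(cols))
  if (!is.null(matched)) {
    midx <- match(as.character(c(matched$pairs$treated_id,
                                 matched$pairs$comparator_id)), ids)
    mg <- rep(c(TRUE, FALSE), each = nrow(matched$pairs))
    d_matched <- vapply(cols, function(j)
      suppressWarnings(smd_crude(X[midx, j], mg)), numeric(1))
  }

  d_str <- rep(NA_real_, length(cols))
  d_wtd <- rep(NA_real_, length(cols))
  if (!is.null(scores) && length(detailed_columns)) {
    for (j in intersect(detailed_columns, cols)) {
      k <- match(j, cols)
      d_str[k] <- suppressWarnings(smd_stratified(X[, j], g1, scores))
      d_wtd[k] <- tryCatch(
        suppressWarnings(smd_weighted(X[, j], g1, scores)),
        error = function(e) NA_real_)
    }
  }

  tab <- data.table::data.table(
    covariate = cols,
    type = ifelse(vapply(cols, function(j) is_binary(X[, j]),
                         logical(1)), "binary", "continuous"),
    d_crude = d_crude, d_matched = d_matched,
    d_stratified = d_str, d_weighted = d_wtd,
    d_crude_pct = 100 * d_crude, d_matched_pct = 100 * d_matched)
  fin <- function(x) x[is.finite(x)]
  summary <- list(
    max_abs_d_crude = max(abs(fin(tab$d_crude)), na.rm = TRUE),
    max_abs_d_matched = if (all(is.na(tab$d_matched))) NA_real_ else
      max(abs(fin(tab$d_matched)), na.rm = TRUE),
    n_crude_gt_2pct = sum(abs(fin(tab$d_crude)) > 0.02),
    n_crude_gt_10pct = sum(abs(fin(tab$d_crude)) > 0.10),
    n_matched_gt_2pct = if (all(is.na(tab$d_matched))) NA_integer_ else
      sum(abs(fin(tab$d_matched)) > 0.02),
    n_matched_gt_10pct = if (all(is.na(tab$d_matched))) NA_integer_ else
      sum(abs(fin(tab$d_matched)) > 0.10))
  list(table = tab, summary = summary)
}
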