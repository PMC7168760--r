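## High-dimensional propensity score machinery: per-dimension empirical
## covariate generation (top-n prevalent codes at once/sporadic/frequent
## within-patient frequency levels), Bross bias-formula prioritization,
## logistic propensity estimation by iteratively reweighted least squares,
## and overlap/trimming diagnostics.

#' Default claims data dimensions for empirical covariate generation
#'
#' Each dimension names a claims table, the code column to scan, and how
#' events are windowed relative to the index admission: `lookback` events
#' must fall inside the lookback window before admission; `before` events
#' (LTD registrations) must simply start before admission.
#'
#' @param top_n_codes number of most prevalent codes retained per dimension
#' @return list of dimension descriptors
#' @export
hdps_dimensions <- function(top_n_codes = 200L) {
  if (top_n_codes < 1) stop_config("top_n_codes must be >= 1")
  mk <- function(name, table, code_col, window) {
    list(name = name, table = table, code_col = code_col, window = window,
         top_n = as.integer(top_n_codes))
  }
  list(
    mk("hospital_diagnosis", "stay_diagnoses", "code", "lookback"),
    mk("drug", "dispensings", "code", "lookback"),
    mk("visit", "visits", "specialty", "lookback"),
    mk("lab", "lab_claims", "code", "lookback"),
    mk("procedure", "stay_procedures", "code", "lookback"),
    mk("ltd", "ltd_registrations", "code", "before"))
}

## long table (patient_id, code, n) of within-window occurrence counts for
## one dimension
dimension_counts <- function(db, cohort, dim, lookback_days) {
  adm <- cohort[, .(patient_id, adm = index_admission_day)]
  tb <- db[[dim$table]]
  if (is.null(tb)) stop_config("dimension '%s' references missing table %s",
                               dim$name, dim$table)
  if (dim$table %in% c("stay_diagnoses", "stay_procedures")) {
    ## window stays by admission day, then join their codes; the primary
    ## diagnosis of each stay also counts in the diagnosis dimension
    stays <- merge(db$hospital_stays, adm, by = "patient_id")
    stays <- stays[admission_day >= adm - lookback_days &
                     admission_day < adm]
    ev <- merge(tb, stays[, .(stay_id, patient_id)],
                by = c("stay_id", "patient_id"))
    ev <- ev[, .(patient_id, code = get(dim$code_col))]
    if (dim$table == "stay_diagnoses") {
      ev <- rbind(ev, stays[, .(patient_id, code = primary_code)])
    }
  } else if (dim$window == "before") {
    ev <- merge(tb, adm, by = "patient_id")[start_day < adm]
    ev <- ev[, .(patient_id, code = get(dim$code_col))]
  } else {
    ev <- merge(tb, adm, by = "patient_id")
    ev <- ev[day >= adm - lookback_days & day < adm,
             .(patient_id, code = get(dim$code_col))]
  }
  if (!nrow(ev)) return(ev[, .(patient_id, code, n = integer())])
  ev[, .(n = .N), by = .(patient_id, code)]
}

## nearest-integer threshold for a quantile of within-user counts
count_threshold <- function(counts, q) {
  as.integer(ceiling(quantile(counts, q, type = 7, names = FALSE)))
}

#' Generate empirical covariates across claims dimensions
#'
#' For each dimension, codes are ranked by the number of distinct cohort
#' patients with at least one occurrence in the window and the `top_n` most
#' prevalent are retained. Each retained code yields up to three binary
#' covariates: once (count >= 1), sporadic (count >= ceiling of the median
#' count among patients with the code) and frequent (count >= ceiling of
#' the 75th-percentile count). Levels whose thresholds coincide collapse
#' into a single covariate (lowest level label kept).
#'
#' @param db a `claims_db`
#' @param cohort analysis cohort (needs patient_id, index_admission_day)
#' @param dimensions list from [hdps_dimensions()]
#' @param lookback_days lookback window before admission
#' @return list with `inventory` (data.table: covariate_id, dimension,
#'   code, level, threshold, n_users, prevalence) and `matrix` (numeric 0/1
#'   matrix, rows = cohort patients in order, columns = covariate_id)
#' @export
generate_empirical_covariates <- function(db, cohort,
                                          dimensions = hdps_dimensions(),
                                          lookback_days = 365L) {
  if (!nrow(cohort)) stop_config("cohort is empty")
  n <- nrow(cohort)
  pid_index <- setNames(seq_len(n), as.character(cohort$patient_id))
  inv <- list()
  cols <- list()
  for (dim in dimensions) {
    cnt <- dimension_counts(db, cohort, dim, lookback_days)
    if (!nrow(cnt)) next
    users <- cnt[, .(n_users = .N), by = code]
    data.table::setorder(users, -n_users, code)
    keep <- users[seq_len(min(dim$top_n, nrow(users)))]
    cnt <- cnt[code %in% keep$code]
    data.table::setkey(cnt, code)
    for (cd in keep$code) {
      cc <- cnt[.(cd)]
      counts <- cc$n
      thr <- c(once = 1L,
               sporadic = count_threshold(counts, 0.5),
               frequent = count_threshold(counts, 0.75))
      thr <- thr[!duplicated(thr)]
      ridx <- pid_index[as.character(cc$patient_id)]
      for (lv in names(thr)) {
        col <- numeric(n)
        col[ridx[counts >= thr[[lv]]]] <- 1
        cid <- paste0(dim$name, ":", cd, ":", lv)
        inv[[cid]] <- list(covariate_id = cid, dimension = dim$name,
                           code = cd, level = lv,
                           threshold = thr[[lv]],
                           n_users = sum(col),
                           prevalence = sum(col) / n)
        cols[[cid]] <- col
      }
    }
  }
  inventory <- data.table::rbindlist(inv)
  mat <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(), n, 0)
  rownames(mat) <- as.character(cohort$patient_id)
  list(inventory = inventory, matrix = mat)
}

#' Bross bias-formula prioritization of empirical covariates
#'
#' For each binary covariate C, computes its prevalence among treated
#' (`p_c1`) and comparator (`p_c0`) patients and the outcome risk ratio
#' across covariate levels in the pooled cohort (`rr_cd`; 0.1 added to
#' every cell of the covariate-outcome table when any cell is zero; when
#' `rr_cd` < 1 its reciprocal is used so protective proxies rank by
#' magnitude). The bias multiplier is
#' `(p_c1 * (rr - 1) + 1) / (p_c0 * (rr - 1) + 1)` and covariates are
#' ranked by the absolute log multiplier, ties broken by higher prevalence
#' then code. Covariates with an undefined multiplier get score 0.
#'
#' @param covariates output of [generate_empirical_covariates()] (or a
#'   compatible list with `inventory` and `matrix`)
#' @param treatment logical/0-1 vector (TRUE = treated arm)
#' @param outcome logical/0-1 vector (endpoint event during follow-up)
#' @param k number of covariates to select (default 500)
#' @return the inventory with columns p_c1, p_c0, rr_cd, bias_score,
#'   rank, selected, ordered by rank
#' @export
prioritize_covariates <- function(covariates, treatment, outcome,
                                  k = 500L) {
  X <- covariates$matrix
  inv <- data.table::copy(covariates$inventory)
  tr <- as.logical(treatment)
  if (anyNA(tr)) stop_config("treatment labels must be binary")
  y <- as.logical(outcome)
  if (length(tr) != nrow(X) || length(y) != nrow(X))
    stop_config("label length does not match covariate matrix")
  if (length(unique(tr)) != 2L)
    stop_config("treatment labels must contain both arms")

  n1 <- sum(tr); n0 <- sum(!tr)
  p_c1 <- colSums(X[tr, , drop = FALSE]) / n1
  p_c0 <- colSums(X[!tr, , drop = FALSE]) / n0

  ## pooled covariate-outcome 2x2 per covariate
  a <- colSums(X[y, , drop = FALSE])        # C=1, D=1
  c1 <- colSums(X) - a                      # C=1, D=0
  b <- sum(y) - a                           # C=0, D=1
  d0 <- sum(!y) - c1                        # C=0, D=0
  zero <- (a == 0) | (b == 0) | (c1 == 0) | (d0 == 0)
  a[zero] <- a[zero] + 0.1; b[zero] <- b[zero] + 0.1
  c1[zero] <- c1[zero] + 0.1; d0[zero] <- d0[zero] + 0.1
  rr <- (a / (a + c1)) / (b / (b + d0))
  rr_use <- ifelse(rr < 1, 1 / rr, rr)
  bm <- (p_c1 * (rr_use - 1) + 1) / (p_c0 * (rr_use - 1) + 1)
  score <- abs(log(bm))
  score[!is.finite(score)] <- 0

  inv[, `:=`(p_c1 = p_c1, p_c0 = p_c0, rr_cd = rr, bias_score = score)]
  data.table::setorder(inv, -bias_score, -prevalence, covariate_id)
  inv[, rank := .I]
  inv[, selected := rank <= min(k, .N)]
  inv[]
}

## exact-duplicate and aliased-column screening for the design matrix
screen_design <- function(X) {
  keep <- rep(TRUE, ncol(X))
  ## constants
  rng <- apply(X, 2, function(z) diff(range(z)))
  const <- rng == 0 & colnames(X) != "(Intercept)"
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(X)[const], collapse = ", "))
    keep[const] <- FALSE
  }
  ## exact duplicates (deterministic projection hash, then verification)
  Xk <- X[, keep, drop = FALSE]
  h <- as.vector(crossprod(Xk, sin(seq_len(nrow(Xk)))))
  dup <- duplicated(round(h, 9))
  if (any(dup)) {
    really <- dup
    for (j in which(dup)) {
      twin <- which(abs(h - h[j]) < 1e-9)
      twin <- twin[twin < j]
      really[j] <- any(vapply(twin, function(t)
        identical(Xk[, t], Xk[, j]), logical(1)))
    }
    if (any(really)) {
      warning("dropping duplicate covariate column(s): ",
              paste(colnames(Xk)[really], collapse = ", "))
      keep[keep][really] <- FALSE
    }
  }
  ## remaining rank deficiency via pivoted Cholesky on the cross-product
  Xk <- X[, keep, drop = FALSE]
  ch <- suppressWarnings(chol(crossprod(Xk), pivot = TRUE))
  r <- attr(ch, "rank")
  if (r < ncol(Xk)) {
    alias <- attr(ch, "pivot")[(r + 1L):ncol(Xk)]
    warning("dropping collinear covariate column(s): ",
            paste(colnames(Xk)[alias], collapse = ", "))
    keep[keep][alias] <- FALSE
  }
  keep
}

#' Fit the propensity model by maximum-likelihood logistic regression
#'
#' IRLS (Newton-Raphson on the binomial log-likelihood) with convergence
#' tolerance 1e-8 and a separation guard: if the fit diverges towards
#' perfect prediction the offending covariates are named in the error.
#' Constant, duplicate and collinear columns are dropped with a warning.
#'
#' @param forced numeric matrix of forced (predefined) covariates
#' @param selected numeric matrix of selected empirical covariates (may
#'   have zero columns)
#' @param treatment logical/0-1 vector, TRUE = treated arm
#' @param tol convergence tolerance on the relative deviance change
#' @param max_iter maximum IRLS iterations
#' @return object of class `hdps_model`: coefficients, fitted per-patient
#'   `score`, kept/dropped column names, deviance, iterations
#' @export
fit_hdps <- function(forced, selected, treatment, tol = 1e-8,
                     max_iter = 100L) {
  y <- as.numeric(treatment)
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(forced) && ncol(forced)) forced,
             if (!is.null(selected) && ncol(selected)) selected)
  keep <- screen_design(X)
  X <- X[, keep, drop = FALSE]

  beta <- numeric(ncol(X))
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    sw <- sqrt(w)
    XtWX <- crossprod(X * sw)
    XtWz <- crossprod(X * sw, z * sw)
    ch <- tryCatch(chol(XtWX), error = function(e)
      chol(XtWX + diag(1e-8 * max(diag(XtWX)), ncol(X))))
    beta_new <- drop(backsolve(ch, forwardsolve(t(ch), XtWz)))
    ## step-halving to keep the deviance decreasing
    dev <- function(b) {
      e <- drop(X %*% b)
      ## numerically stable -2 log-likelihood
      -2 * sum(y * e - (pmax(e, 0) + log1p(exp(-abs(e)))))
    }
    d_new <- dev(beta_new)
    half <- 0L
    while (!is.finite(d_new) || d_new > dev_old + 1e-8) {
      half <- half + 1L
      if (half > 30L) break
      beta_new <- (beta + beta_new) / 2
      d_new <- dev(beta_new)
    }
    beta <- beta_new
    if (d_new < 1e-6) {
      ## perfect separation: the model predicts every label exactly and
      ## the likelihood has no finite maximizer
      worst <- order(-abs(beta))[seq_len(min(5L, length(beta)))]
      stop_config(paste0(
        "separation detected while fitting the propensity model; ",
        "offending covariate(s): %s"),
        paste(setdiff(colnames(X)[worst], "(Intercept)"),
              collapse = ", "))
    }
    if (abs(dev_old - d_new) < tol * (abs(d_new) + 0.1)) {
      dev_old <- d_new
      break
    }
    dev_old <- d_new
  }
  score <- plogis(drop(X %*% beta))
  structure(list(coefficients = setNames(beta, colnames(X)),
                 score = score, kept = colnames(X),
                 dropped = setdiff(colnames(cbind(`(Intercept)` = 1,
                                                  forced, selected)),
                                   colnames(X)),
                 deviance = dev_old, iterations = it,
                 n = n, treated_fraction = mean(y)),
            class = "hdps_model")
}

#' @export
print.hdps_model <- function(x, ...) {
  cat("<hdps_model>", length(x$coefficients), "coefficients,", x$n,
      "patients, deviance", format(x$deviance, digits = 6), "\n")
  invisible(x)
}

#' Trim patients outside the region of score overlap
#'
#' The common-support rule keeps scores between the larger of the two
#' within-arm minima and the smaller of the two within-arm maxima. The
#' percentile rule keeps scores between the given pooled percentiles.
#'
#' @param score numeric vector of fitted scores
#' @param treatment logical vector
#' @param rule "common_support" or "percentile"
#' @param percentiles length-2 bounds for the percentile rule
#' @return logical keep vector
#' @export
trim_scores <- function(score, treatment,
                        rule = c("common_support", "percentile"),
                        percentiles = c(0.01, 0.99)) {
  rule <- match.arg(rule)
  tr <- as.logical(treatment)
  if (rule == "common_support") {
    lo <- max(min(score[tr]), min(score[!tr]))
    hi <- min(max(score[tr]), max(score[!tr]))
  } else {
    q <- quantile(score, percentiles, names = FALSE)
    lo <- q[1]; hi <- q[2]
  }
  keep <- score >= lo & score <= hi
  if (!any(keep[tr]) || !any(keep[!tr]))
    stop_config("trimming emptied a treatment arm")
  keep
}
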