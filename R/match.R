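## 1:1 matching within calipers: exact on gender and index-diagnosis
## stratum, age within +/-1 year, propensity score within +/-0.05, without
## replacement. Greedy mode processes treated patients in descending score
## order, each taking the eligible comparator with the smallest score
## distance; optimal mode minimizes the total score distance over a
## bipartite assignment restricted to caliper-eligible pairs.

#' Matching specification
#'
#' @param exact covariates matched exactly (default gender and stratum)
#' @param age_caliper maximum |age difference| in years (inclusive)
#' @param score_caliper maximum |score difference| (inclusive)
#' @param algorithm "greedy_nearest" or "optimal"
#' @param seed integer, recorded for provenance (both algorithms are
#'   deterministic given their inputs)
#' @return object of class `match_spec`
#' @export
match_spec <- function(exact = c("gender", "stratum"), age_caliper = 1,
                       score_caliper = 0.05,
                       algorithm = c("greedy_nearest", "optimal"),
                       seed = 1L) {
  if (age_caliper <= 0 || score_caliper <= 0)
    stop_config("calipers must be > 0")
  structure(list(exact = exact, age_caliper = age_caliper,
                 score_caliper = score_caliper,
                 algorithm = match.arg(algorithm),
                 seed = as.integer(seed)),
            class = "match_spec")
}

## shortest-augmenting-path linear assignment (Jonker-Volgenant style);
## rows must not outnumber columns; returns for each row its column
lap_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(Inf, m); used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1L] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

## large pseudo-cost standing in for an ineligible pair; any real score
## distance (<= 1) is infinitely preferred
BIG_COST <- 1e6

match_cell_greedy <- function(tr, co, age_cal, score_cal) {
  ord <- order(-tr$score, tr$patient_id)
  used <- rep(FALSE, nrow(co))
  out <- vector("list", nrow(tr))
  for (k in ord) {
    ds <- abs(co$score - tr$score[k])
    da <- abs(co$age_years - tr$age_years[k])
    elig <- which(!used & ds <= score_cal & da <= age_cal)
    if (!length(elig)) next
    o <- elig[order(ds[elig], da[elig], co$patient_id[elig])][1L]
    used[o] <- TRUE
    out[[k]] <- list(treated_id = tr$patient_id[k],
                     comparator_id = co$patient_id[o],
                     delta_score = ds[o], delta_age = da[o])
  }
  data.table::rbindlist(out)
}

match_cell_optimal <- function(tr, co, age_cal, score_cal) {
  nt <- nrow(tr); nc <- nrow(co)
  if (nt > 600L || nc > 600L)
    stop_config("optimal matching is limited to cells of <= 600 patients; use the greedy algorithm")
  cost <- abs(outer(tr$score, co$score, "-"))
  bad <- abs(outer(tr$age_years, co$age_years, "-")) > age_cal |
    cost > score_cal
  cost[bad] <- BIG_COST
  flip <- FALSE
  if (nt > nc) { cost <- t(cost); flip <- TRUE }
  a <- lap_assign(cost)
  rows <- seq_along(a)
  keep <- cost[cbind(rows, a)] < BIG_COST / 2
  ti <- if (flip) a[keep] else rows[keep]
  ci <- if (flip) rows[keep] else a[keep]
  data.table::data.table(
    treated_id = tr$patient_id[ti], comparator_id = co$patient_id[ci],
    delta_score = abs(tr$score[ti] - co$score[ci]),
    delta_age = abs(tr$age_years[ti] - co$age_years[ci]))
}

#' 1:1 caliper matching of treated to comparator patients
#'
#' @param data data.table with patient_id, score, age_years, the exact-key
#'   columns, and `arm` (logical or the treated level of `treated_arm`)
#' @param spec a [match_spec()]
#' @param treated logical vector marking the treated arm (same order as
#'   `data`)
#' @return object of class `matched_cohort`: `pairs` (treated_id,
#'   comparator_id, delta_score, delta_age, pair_id), `n_unmatched`
#'   (named: treated, comparator), and the spec
#' @export
match_cohort <- function(data, treated, spec = match_spec()) {
  treated <- as.logical(treated)
  if (!any(treated) || all(treated)) stop_config("a treatment arm is empty")
  d <- data.table::as.data.table(data)
  d[, .trt := treated]
  cell_key <- do.call(paste, c(lapply(spec$exact, function(k) d[[k]]),
                               sep = "|"))
  d[, .cell := cell_key]
  pairs <- list()
  for (cl in sort(unique(d$.cell))) {
    tr <- d[.cell == cl & .trt == TRUE]
    co <- d[.cell == cl & .trt == FALSE]
    if (!nrow(tr) || !nrow(co)) next
    pairs[[cl]] <- if (spec$algorithm == "greedy_nearest") {
      match_cell_greedy(tr, co, spec$age_caliper, spec$score_caliper)
    } else {
      match_cell_optimal(tr, co, spec$age_caliper, spec$score_caliper)
    }
  }
  pairs <- data.table::rbindlist(pairs)
  if (!nrow(pairs))
    pairs <- data.table::data.table(treated_id = integer(),
                                    comparator_id = integer(),
                                    delta_score = numeric(),
                                    delta_age = numeric())
  data.table::setorder(pairs, treated_id)
  pairs[, pair_id := .I]
  structure(list(
    pairs = pairs,
    n_unmatched = c(treated = sum(treated) - nrow(pairs),
                    comparator = sum(!treated) - nrow(pairs)),
    spec = spec), class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("<matched_cohort>", nrow(x$pairs), "pairs |", x$n_unmatched[1],
      "unmatched treated |", x$n_unmatched[2], "unmatched comparators\n")
  invisible(x)
}
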