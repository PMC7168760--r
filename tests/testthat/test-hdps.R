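## small cohort table for covariate generation fixtures
hdps_cohort <- function(n) {
  data.table(patient_id = seq_len(n),
             index_admission_day = rep(450L, n))
}

hdps_db <- function(n_pat, lab_rows) {
  pats <- do.call(rbind, lapply(seq_len(n_pat), patient_row))
  make_claims_db(patients = pats, lab_claims = lab_rows)
}

test_that("frequency levels collapse when thresholds coincide", {
  ## one occurrence for every patient: median = p75 = 1 -> one covariate
  labs <- data.table(patient_id = 1:6, day = 400L, code = "LAB1")
  db <- hdps_db(6, labs)
  g <- generate_empirical_covariates(db, hdps_cohort(6))
  expect_equal(nrow(g$inventory), 1L)
  expect_equal(g$inventory$level, "once")
  expect_equal(unname(colSums(g$matrix)), 6)
})

test_that("sporadic/frequent thresholds use ceiling quantiles of user counts", {
  ## per-patient counts {1, 1, 2, 4}: median 1.5 -> >=2, p75 2.5 -> >=3
  reps <- rep(1:4, c(1, 1, 2, 4))
  labs <- data.table(patient_id = reps,
                     day = 400L + seq_along(reps), code = "LAB1")
  db <- hdps_db(4, labs)
  g <- generate_empirical_covariates(db, hdps_cohort(4))
  expect_equal(g$inventory$threshold, c(1L, 2L, 3L))
  expect_equal(g$inventory$level, c("once", "sporadic", "frequent"))
  expect_equal(unname(colSums(g$matrix)), c(4, 2, 1))
})

test_that("empty dimensions yield no covariates and top_n caps the codes", {
  labs <- data.table(patient_id = rep(1:4, each = 3),
                     day = 400L,
                     code = rep(c("A", "B", "C"), 4))
  db <- hdps_db(4, labs)
  g <- generate_empirical_covariates(db, hdps_cohort(4),
                                     hdps_dimensions(top_n_codes = 2))
  expect_equal(sort(unique(g$inventory$code)), c("A", "B"))
  expect_true(all(g$inventory$dimension == "lab"))
})

test_that("Bross prioritization matches hand calculations and trivial nulls", {
  ## engineered labels: P_C1 = 0.4, P_C0 = 0.2, RR_CD = 2 exactly
  n1 <- 20; n0 <- 20
  treated <- rep(c(TRUE, FALSE), c(n1, n0))
  C <- c(rep(1, 8), rep(0, 12), rep(1, 4), rep(0, 16))
  Y <- integer(40)
  Y[which(C == 1)[1:6]] <- 1          # 6 of 12 exposed -> risk 0.5
  Y[which(C == 0)[1:7]] <- 1          # 7 of 28 unexposed -> risk 0.25
  cov <- list(
    inventory = data.table(covariate_id = "c1", dimension = "lab",
                           code = "c1", level = "once", threshold = 1L,
                           n_users = sum(C), prevalence = mean(C)),
    matrix = matrix(C, ncol = 1, dimnames = list(NULL, "c1")))
  pr <- prioritize_covariates(cov, treated, Y)
  expect_equal(pr$p_c1, 0.4)
  expect_equal(pr$p_c0, 0.2)
  expect_equal(pr$rr_cd, 2)
  expect_equal(pr$bias_score, abs(log((0.4 * 1 + 1) / (0.2 * 1 + 1))),
               tolerance = 1e-12)

  ## no exposure association => score 0
  C2 <- rep(c(1, 0), 20)
  cov$matrix[, 1] <- C2
  pr <- prioritize_covariates(cov, treated, Y)
  expect_equal(pr$bias_score, 0)
  ## no outcome association => score 0 (risk identical across C)
  C3 <- c(rep(1, 10), rep(0, 10), rep(1, 10), rep(0, 10))
  Y3 <- rep(c(1, 0, 1, 0, 0), 8)
  cov$matrix[, 1] <- C3
  pr <- prioritize_covariates(cov, treated, Y3)
  expect_equal(pr$rr_cd, 1)
  expect_equal(pr$bias_score, 0)
})

test_that("prioritization agrees with a brute-force 2x2 oracle", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(50:200, 1)
    p <- sample(3:10, 1)
    X <- matrix(rbinom(n * p, 1, runif(p, 0.1, 0.7)[rep(1:p, each = n)]),
                n, p, dimnames = list(NULL, paste0("c", 1:p)))
    treated <- as.logical(rbinom(n, 1, 0.5))
    if (length(unique(treated)) < 2) next
    y <- as.logical(rbinom(n, 1, 0.3))
    cov <- list(
      inventory = data.table(covariate_id = paste0("c", 1:p),
                             dimension = "lab", code = paste0("c", 1:p),
                             level = "once", threshold = 1L,
                             n_users = colSums(X),
                             prevalence = colMeans(X)),
      matrix = X)
    pr <- prioritize_covariates(cov, treated, y)
    for (j in 1:p) {
      expect_equal(pr[covariate_id == paste0("c", j), bias_score],
                   oracle_bross(X[, j], treated, y), tolerance = 1e-12)
    }
  }
})

test_that("selection keeps exactly k covariates and is permutation invariant", {
  set.seed(5)
  n <- 300; p <- 600
  X <- matrix(rbinom(n * p, 1, 0.3), n, p,
              dimnames = list(NULL, sprintf("c%03d", 1:p)))
  treated <- as.logical(rbinom(n, 1, 0.5))
  y <- as.logical(rbinom(n, 1, 0.3))
  cov <- list(
    inventory = data.table(covariate_id = colnames(X), dimension = "lab",
                           code = colnames(X), level = "once",
                           threshold = 1L, n_users = colSums(X),
                           prevalence = colMeans(X)),
    matrix = X)
  pr <- prioritize_covariates(cov, treated, y, k = 500)
  expect_equal(sum(pr$selected), 500L)

  perm <- sample(n)
  cov2 <- cov; cov2$matrix <- X[perm, ]
  pr2 <- prioritize_covariates(cov2, treated[perm], y[perm], k = 500)
  expect_equal(pr2$covariate_id, pr$covariate_id)
  expect_equal(pr2$bias_score, pr$bias_score)

  ## swapping arm labels inverts the multiplier, |log| unchanged
  pr3 <- prioritize_covariates(cov, !treated, y, k = 500)
  expect_equal(pr3[order(covariate_id), bias_score],
               pr[order(covariate_id), bias_score], tolerance = 1e-12)
})

test_that("propensity fitting handles the degenerate and separated cases", {
  set.seed(17)
  n <- 200
  treated <- rep(c(TRUE, FALSE), each = n / 2)
  ## intercept-only: every score equals the treated fraction
  m <- fit_hdps(NULL, NULL, treated)
  expect_equal(unname(m$score), rep(0.5, n), tolerance = 1e-8)
  ## a covariate identical to treatment: perfect separation
  sep <- matrix(as.numeric(treated), ncol = 1,
                dimnames = list(NULL, "twin"))
  expect_error(fit_hdps(NULL, sep, treated), "separation")
  ## constant and duplicated columns are dropped with a warning
  X <- cbind(a = rbinom(n, 1, 0.4), b = rep(1, n))
  X <- cbind(X, c = X[, "a"])
  expect_warning(expect_warning(m2 <- fit_hdps(NULL, X, treated),
                                "constant"), "duplicate")
  expect_false(any(c("b", "c") %in% m2$kept))
  ## fitted scores agree with stats::glm on a well-posed problem
  Xg <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("x1", "x2",
                                                           "x3")))
  yb <- rbinom(n, 1, plogis(0.3 + Xg %*% c(0.5, -0.4, 0.2)))
  m3 <- fit_hdps(NULL, Xg, yb)
  g <- glm(yb ~ Xg, family = binomial())
  expect_equal(unname(m3$coefficients), unname(coef(g)),
               tolerance = 1e-6)
})

test_that("trimming rules implement common support and percentiles", {
  score <- c(0.1, 0.2, 0.3, 0.4, 0.9, 0.15, 0.25, 0.35, 0.45, 0.5)
  treated <- rep(c(TRUE, FALSE), each = 5)
  keep <- trim_scores(score, treated, "common_support")
  ## treated max 0.9 above all comparators -> trimmed; bounds
  ## [max(mins), min(maxes)] = [0.15, 0.5]
  expect_false(keep[5])
  expect_false(keep[1])
  expect_true(all(keep[c(2, 3, 4, 6, 7, 8, 9, 10)]))

  ## identical distributions: nothing trimmed
  s2 <- rep(c(0.2, 0.4, 0.6), 2)
  t2 <- rep(c(TRUE, FALSE), each = 3)
  expect_true(all(trim_scores(s2, t2, "common_support")))

  ## percentile rule against a quantile oracle
  set.seed(3)
  s3 <- runif(500)
  t3 <- rep(c(TRUE, FALSE), 250)
  keep3 <- trim_scores(s3, t3, "percentile", percentiles = c(0.01, 0.99))
  q <- quantile(s3, c(0.01, 0.99), names = FALSE)
  expect_equal(sum(!keep3), sum(s3 < q[1] | s3 > q[2]))

  expect_error(trim_scores(c(0.1, 0.2, 0.8, 0.9),
                           c(TRUE, TRUE, FALSE, FALSE), "percentile",
                           percentiles = c(0.49, 0.51)), "emptied")
})
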