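dict <- drug_dictionary()

test_that("treatment group is the first study drug dispensed within 30 days", {
  d <- disp_row(1, 5, "B01AC24")
  g <- assign_treatment_group(d, index_date = 0, dict)
  expect_equal(g$initial_family, "ticagrelor")
  expect_false(g$asa_at_index)

  ## first study dispensing beyond day 30: not included
  expect_null(assign_treatment_group(disp_row(1, 31, "B01AC04"),
                                     index_date = 0, dict))
  ## no study drug at all
  expect_null(assign_treatment_group(disp_row(1, 5, "B01AC06"),
                                     index_date = 0, dict))
  ## history dispensings before index do not define the group
  d <- rbind(disp_row(1, 100, "B01AC04"), disp_row(1, 400, "B01AC24"))
  g <- assign_treatment_group(d, index_date = 395, dict)
  expect_equal(g$initial_family, "ticagrelor")
  ## ASA on the first dispensing day sets the flag
  d <- rbind(disp_row(1, 5, "B01AC24"), disp_row(1, 5, "B01AC06"))
  expect_true(assign_treatment_group(d, 0, dict)$asa_at_index)
  expect_error(assign_treatment_group(disp_row(1, -3), 0, dict),
               "negative")
})

test_that("episode tracking matches the published worked cases", {
  ## one 30-unit pack at day 0, nothing else: discontinuation at
  ## last dispensing + supply = day 30, exposure 30 days
  ep <- track_episode(disp_row(1, 0), 0, "ticagrelor", 0, dict)
  expect_equal(ep$discontinuation_day, 30L)
  expect_equal(ep$exposure_days, 30L)
  expect_equal(ep$mpr_percent, 100)

  ## refills every 25 days: stock carryover grows 5 days per cycle,
  ## no discontinuation over the year
  days <- seq(0, 350, by = 25)
  d <- do.call(rbind, lapply(days, function(x) disp_row(1, x)))
  ep <- track_episode(d, 0, "ticagrelor", 0, dict)
  expect_true(is.na(ep$discontinuation_day))
  expect_equal(ep$exposure_days, 365L)

  ## switch: clopidogrel at 0, ticagrelor at 40
  d <- rbind(disp_row(1, 0, "B01AC04"), disp_row(1, 40, "B01AC24"))
  ep <- track_episode(d, 0, "clopidogrel", 0, dict)
  expect_equal(ep$switch_day, 40L)
  expect_equal(ep$retention_day, 40L)

  ## MPR capped at 100: 400 DDD over a full-year exposure
  days <- seq(0, 330, by = 30)
  d <- do.call(rbind, lapply(days, function(x)
    disp_row(1, x, units = 40L)))
  ep <- track_episode(d, 0, "ticagrelor", 0, dict)
  expect_equal(ep$exposure_days, 365L)
  expect_equal(ep$mpr_percent, 100)

  ## unknown code errors
  d <- disp_row(1, 0, "XXX999")
  expect_error(track_episode(d, 0, "ticagrelor", 0, dict), "missing")
})

test_that("episode tracking agrees with a day-by-day stock oracle", {
  set.seed(77)
  for (rep in 1:150) {
    nd <- sample(1:12, 1)
    own_days <- sort(sample(0:250, nd))
    own_days <- own_days - own_days[1] + sample(0:20, 1)
    supplies <- sample(c(7L, 10L, 30L, 60L), nd, replace = TRUE)
    other_days <- if (runif(1) < 0.4)
      sample(own_days[1] + 1:330, sample(1:2, 1)) else integer()
    death <- if (runif(1) < 0.15) own_days[1] + sample(30:400, 1) else
      NA_integer_
    d <- do.call(rbind, c(
      lapply(seq_len(nd), function(i)
        disp_row(1, own_days[i], "B01AC24", units = supplies[i])),
      lapply(other_days, function(x) disp_row(1, x, "B01AC04"))))
    ep <- track_episode(d, 0, "ticagrelor", own_days[1], dict,
                        death_day = death)
    or <- oracle_episode(own_days, supplies, other_days,
                         index_date = 0, death_day = death)
    expect_equal(ep$discontinuation_day, or$discontinuation_day,
                 info = paste("rep", rep))
    expect_equal(ep$switch_day, or$switch_day, info = paste("rep", rep))
    expect_equal(ep$retention_day, or$retention_day,
                 info = paste("rep", rep))
    expect_equal(ep$exposure_end_day, as.integer(or$exposure_end_day),
                 info = paste("rep", rep))
  }
})

test_that("adding a dispensing never moves discontinuation earlier", {
  set.seed(88)
  for (rep in 1:60) {
    nd <- sample(1:8, 1)
    own_days <- sort(sample(0:300, nd))
    d <- do.call(rbind, lapply(own_days, function(x) disp_row(1, x)))
    ep0 <- track_episode(d, 0, "ticagrelor", own_days[1], dict)
    extra_day <- sample(setdiff(own_days[1]:360, own_days), 1)
    d2 <- rbind(d, disp_row(1, extra_day))
    ep1 <- track_episode(d2, 0, "ticagrelor", own_days[1], dict)
    d0 <- ifelse(is.na(ep0$discontinuation_day), Inf,
                 ep0$discontinuation_day)
    d1 <- ifelse(is.na(ep1$discontinuation_day), Inf,
                 ep1$discontinuation_day)
    expect_gte(d1, d0)
  }
})

test_that("MPR categories partition [0, 100] with singleton endpoints", {
  sweep <- seq(0, 100, by = 10)
  cats <- mpr_category(sweep)
  expect_equal(length(levels(cats)), 7L)
  expect_equal(as.character(cats[sweep == 0]), "0")
  expect_equal(as.character(cats[sweep == 100]), "100")
  ## every value falls in exactly one category
  fine <- seq(0, 100, by = 0.25)
  expect_false(anyNA(mpr_category(fine)))
  expect_equal(as.character(mpr_category(19.999)), "]0-20[")
  expect_equal(as.character(mpr_category(20)), "[20-40[")
  expect_equal(as.character(mpr_category(99.999)), "[80-100[")
  expect_error(mpr_category(101), "within")
})
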