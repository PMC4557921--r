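# Survey tabulation, harmonization rules, and logit transforms.

test_that("weighted tabulation reproduces hand-computed weighted means", {
  # equal weights: plain mean
  est <- weighted_tabulate(make_microdata(c(1, 0, 1, 1)), itn_def())
  expect_equal(est$p, 0.75)

  # weights {3, 1} on outcomes {1, 0}: (3*1 + 1*0) / 4
  est2 <- weighted_tabulate(make_microdata(c(1, 0), weights = c(3, 1)),
                            itn_def())
  expect_equal(est2$p, 0.75)

  # one estimate per (state, year) present in the data
  rec <- dplyr::bind_rows(
    make_microdata(c(1, 0), state = "Lagos", event_year = 2010),
    make_microdata(c(1, 1), state = "Kano", zone = "North West",
                   event_year = 2008)
  )
  est3 <- weighted_tabulate(rec, itn_def())
  expect_equal(nrow(est3), 2L)
  expect_setequal(est3$state, c("Lagos", "Kano"))
})

test_that("tabulation is invariant to uniform weight rescaling", {
  w <- runif(50, 0.5, 2)
  o <- rbinom(50, 1, 0.4)
  a <- weighted_tabulate(make_microdata(o, weights = w), itn_def())
  b <- weighted_tabulate(make_microdata(o, weights = 7.3 * w), itn_def())
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$var_p, b$var_p, tolerance = 1e-12)
})

test_that("ratio-estimator variance tracks the binomial variance", {
  withr::with_seed(11, {
    o <- rbinom(200, 1, 0.6)
    est <- weighted_tabulate(make_microdata(o), itn_def())
    p <- mean(o)
    expect_equal(est$var_p, p * (1 - p) / 200, tolerance = 0.1)
  })
})

test_that("mean tabulated variance is calibrated over repeated surveys", {
  # 1,000 surveys of n = 500 at deff = 1: mean var_p within 5% of p(1-p)/n
  withr::with_seed(7, {
    p_true <- 0.35
    n <- 500
    vars <- vapply(1:1000, function(i) {
      o <- rbinom(n, 1, p_true)
      weighted_tabulate(make_microdata(o), itn_def())$var_p
    }, numeric(1))
    expect_equal(mean(vars), p_true * (1 - p_true) / n, tolerance = 0.05)
  })
})

test_that("tabulation rejects malformed weights and clamps extremes", {
  expect_error(weighted_tabulate(make_microdata(c(1, 0), weights = c(0, 0)),
                                 itn_def()),
               "weights")
  expect_error(weighted_tabulate(make_microdata(c(1, 0), weights = c(-1, 1)),
                                 itn_def()),
               "positive")
  # all-1 cell is clamped inside (0, 1) with positive variance
  est <- weighted_tabulate(make_microdata(rep(1, 10)), itn_def())
  expect_lt(est$p, 1)
  expect_gt(est$var_p, 0)
  # empty group: no estimate, no error
  expect_equal(nrow(weighted_tabulate(make_microdata(numeric(0)),
                                      itn_def())), 0L)
})

test_that("event-year attribution follows the indicator convention", {
  rec <- tibble::tibble(
    survey_id = "dhs2008", state = "Lagos", zone = "South West",
    weight = 1, outcome = 1, survey_year = 2008,
    birth_year = c(2005, NA, 2007)
  )
  expect_message(out <- attribute_event_year(rec, sba_def()), "dropped 1")
  expect_equal(out$event_year, c(2005, 2007))
  expect_equal(attr(out, "n_dropped"), 1L)

  # survey-year indicators keep the survey year
  rec$birth_year <- NULL
  out2 <- attribute_event_year(rec, itn_def())
  expect_equal(out2$event_year, rep(2008, 3))
  expect_equal(attr(out2, "n_dropped"), 0L)
})

test_that("recall windows differ by source family", {
  rec <- tibble::tibble(
    survey_id = "x", state = "Lagos", zone = "South West", weight = 1,
    outcome = 1, survey_year = c(2013, 2013, 2011, 2011),
    birth_year = c(2007, 2006, 2009, 2008)
  )
  expect_equal(window_filter(rec, "full-history")$birth_year,
               c(2007, 2009, 2008))
  expect_equal(window_filter(rec[3:4, ], "recent-birth-only")$birth_year,
               2009)
  expect_equal(nrow(window_filter(rec[0, ], "full-history")), 0L)
})

test_that("card crosswalk scales the estimate and its variance", {
  expect_equal(estimate_crosswalk_ratio(
    tibble::tibble(card_only_p = c(0.5, 0.4), total_p = c(0.6, 0.48))), 1.2)
  expect_equal(estimate_crosswalk_ratio(
    tibble::tibble(card_only_p = 0.5, total_p = 0.5)), 1.0)
  expect_error(estimate_crosswalk_ratio(
    tibble::tibble(card_only_p = 0, total_p = 0.5)))
  expect_error(estimate_crosswalk_ratio(
    tibble::tibble(card_only_p = numeric(0), total_p = numeric(0))))

  est <- tibble::tibble(indicator = "measles", state = "Kano",
                        zone = "North West", year = 2007, p = 0.40,
                        var_p = 0.001, source_id = "mics2007", flags = "")
  adj <- card_crosswalk(est, 1.2)
  expect_equal(adj$p, 0.48)
  expect_equal(adj$var_p, 0.001 * 1.2^2)
  expect_true(has_flag(adj$flags, "card_only_adjusted"))

  # identity ratio changes nothing but the flag; large products clamp
  expect_equal(card_crosswalk(est, 1)$p, 0.40)
  est$p <- 0.90
  expect_equal(card_crosswalk(est, 1.2)$p, 0.999)
  expect_error(card_crosswalk(est, -1), "positive")
})

test_that("pre-policy imputation emits near-zero pseudo-observations", {
  grid <- 2000:2013
  itn <- impute_pre_policy(itn_def(), "Lagos", 1998:2013)
  expect_true(all(itn$year < 2000))
  expect_true(all(itn$p == 1e-4 & itn$var_p == 1e-8))
  expect_true(all(has_flag(itn$flags, "imputed_pre_policy")))

  iptp <- impute_pre_policy(indicator_definition("iptp2"), "Kano", grid)
  expect_equal(iptp$year, 2000L)       # only the pre-2001 grid year
  expect_false(2005 %in% iptp$year)

  # per-state roll-out overrides the national year
  irs <- impute_pre_policy(
    indicator_definition("itn_irs"), c("Lagos", "Kano"), grid,
    policy_table = tibble::tibble(state = "Kano", policy_start_year = 2006))
  expect_equal(sort(unique(irs$year[irs$state == "Kano"])), 2000:2005)
  expect_equal(nrow(irs[irs$state == "Lagos", ]), 0L)

  expect_error(impute_pre_policy(sba_def(), "Lagos", grid), "policy")
})

test_that("exclusion flags are configuration-driven and kept out of fits", {
  est <- tibble::tibble(
    indicator = "measles", state = c("Kano", "Lagos"), zone = "z",
    year = 2007, p = 0.4, var_p = 0.001,
    source_id = c("svyX", "svyY"), flags = ""
  )
  expect_message(
    out <- flag_exclusions(est, tibble::tibble(indicator = "measles",
                                               state = "Kano",
                                               source_id = "svyX")),
    "50.0%")
  expect_true(has_flag(out$flags[1], "excluded"))
  expect_false(has_flag(out$flags[2], "excluded"))
  expect_equal(nrow(drop_excluded(out)), 1L)
  # empty list: identity
  expect_identical(flag_exclusions(est, est[0, c("indicator", "state",
                                                 "source_id")]), est)
})

test_that("logit transform applies the delta method and round-trips", {
  expect_equal(to_logit(0.5, 0.01)$y, 0)
  expect_equal(to_logit(0.5, 0.01)$var_y, 0.16)   # 0.01 / 0.25^2
  expect_equal(to_logit(0.73, 0.01)$y, log(0.73 / 0.27), tolerance = 1e-10)
  expect_error(to_logit(1.2, 0.01))
  expect_error(to_logit(0.5, -1))

  p <- seq(0.001, 0.999, length.out = 41)
  var_p <- runif(41, 1e-5, 1e-3)
  lg <- to_logit(p, var_p)
  back <- from_logit(lg$y, lg$var_y)
  expect_equal(back$p, p, tolerance = 1e-10)
  expect_equal(back$var_p, var_p, tolerance = 1e-10)
})

test_that("the indicator registry satisfies its structural contracts", {
  reg <- indicator_registry()
  expect_equal(nrow(reg), 20L)
  expect_equal(sum(reg$composite_member), 11L)
  # policy years only on the malaria interventions with documented adoption
  expect_setequal(reg$id[!is.na(reg$policy_start_year)],
                  c("itn_own", "itn_irs", "iptp2", "act"))
  expect_equal(reg$composite_transform[reg$id == "wasting"], "complement")
  # states: 37 units, each in exactly one of 6 zones
  st <- nigeria_states()
  expect_equal(nrow(st), 37L)
  expect_equal(dplyr::n_distinct(st$zone), 6L)
  expect_equal(anyDuplicated(st$state), 0L)
})
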