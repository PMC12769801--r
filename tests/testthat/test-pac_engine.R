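test_that("condition 1 combines primary concepts cumulatively across notes", {
  ev <- build_evidence("P1", mk_mentions(c("cough", "wheezing"),
                                         c("2002-01-10", "2002-03-05")))
  expect_equal(ev$cond1_date, as.Date("2002-03-05"))

  # wheeze at examination route with dyspnea
  ev <- build_evidence("P1", mk_mentions(c("dyspnea", "wheeze_on_exam"),
                                         c("2002-05-01", "2002-02-01")))
  expect_equal(ev$cond1_date, as.Date("2002-05-01"))

  # negated evidence is never credited
  ev <- build_evidence("P1", mk_mentions(c("cough", "wheezing"),
                                         c("2002-01-10", "2002-03-05"),
                                         assertion = "negated"))
  expect_true(is.na(ev$cond1_date))

  # a lone symptom never completes condition 1
  ev <- build_evidence("P1", mk_mentions("wheezing", "2002-01-10"))
  expect_true(is.na(ev$cond1_date))

  expect_error(build_evidence("P1", mk_mentions("cough", "2002-01-01",
                                                patient_id = "P9")),
               "foreign patient_id")
})

test_that("eosinophilia requires a count strictly above 300 cells/uL", {
  ev <- build_evidence("P1", no_mentions(),
                       mk_obs("eosinophil_count", "2003-04-01", 300))
  expect_true(is.na(ev$minor_dates[["eosinophilia_gt300"]]))
  ev <- build_evidence("P1", no_mentions(),
                       mk_obs("eosinophil_count", "2003-04-01", 301))
  expect_equal(ev$minor_dates[["eosinophilia_gt300"]],
               as.Date("2003-04-01"))
})

test_that("nonsmoker criterion waits for the 14th birthday", {
  obs <- mk_obs("smoking_status", "2003-06-01", "never")
  ev <- build_evidence("P1", no_mentions(), obs,
                       birth_date = as.Date("1990-05-01"))
  expect_equal(ev$minor_dates[["nonsmoker_14plus"]], as.Date("2004-05-01"))
  # adult at documentation: credited at the observation date
  ev <- build_evidence("P1", no_mentions(), obs,
                       birth_date = as.Date("1960-05-01"))
  expect_equal(ev$minor_dates[["nonsmoker_14plus"]], as.Date("2003-06-01"))
  # current/former fail by default; 'former' admitted only by config
  obs2 <- mk_obs("smoking_status", "2003-06-01", "former")
  ev <- build_evidence("P1", no_mentions(), obs2,
                       birth_date = as.Date("1960-05-01"))
  expect_true(is.na(ev$minor_dates[["nonsmoker_14plus"]]))
  ev <- build_evidence("P1", no_mentions(), obs2,
                       birth_date = as.Date("1960-05-01"),
                       config = pac_config(admit_former_smoker = TRUE))
  expect_equal(ev$minor_dates[["nonsmoker_14plus"]], as.Date("2003-06-01"))
})

test_that("pulmonary function criterion follows the low/improvement rule", {
  obs <- rbind(mk_obs("fev1_pct_pred", "2001-05-01", 65),
               mk_obs("fev1_bd_improvement", "2001-06-01", 22),
               mk_obs("fev1_post_bd_pct_pred", "2001-06-01", 79))
  expect_equal(eval_pft_criterion(obs), as.Date("2001-06-01"))

  # methacholine decline of exactly 20% qualifies (inclusive boundary)
  expect_equal(eval_pft_criterion(
    mk_obs("methacholine_fev1_decline", "2004-02-02", 20)),
    as.Date("2004-02-02"))
  expect_true(is.na(eval_pft_criterion(
    mk_obs("methacholine_fev1_decline", "2004-02-02", 19.5))))

  # a lone normal spirometry satisfies nothing
  expect_true(is.na(eval_pft_criterion(
    mk_obs("fev1_pct_pred", "2001-05-01", 72))))
  expect_true(is.na(eval_pft_criterion(no_obs())))

  # paired spirometries: 62 -> 80 is a 29% improvement above 70% predicted
  obs <- rbind(mk_obs("fev1_pct_pred", "2001-05-01", 62),
               mk_obs("fev1_pct_pred", "2001-08-01", 80))
  expect_equal(eval_pft_criterion(obs), as.Date("2001-08-01"))
  # improvement below 20% does not qualify (72 -> 80 is 11%)
  obs <- rbind(mk_obs("fev1_pct_pred", "2001-05-01", 68),
               mk_obs("fev1_pct_pred", "2001-08-01", 75))
  expect_true(is.na(eval_pft_criterion(obs)))
})

test_that("classification follows the definite/probable/exclusion rules", {
  dx_only <- build_evidence("P1", mk_mentions("physician_asthma_dx",
                                              "2005-03-03",
                                              section = "diagnosis"))
  st <- classify(dx_only)
  expect_equal(st$granular, "definite")
  expect_true(st$asthma)
  expect_equal(st$index_date, as.Date("2005-03-03"))

  # diagnosis concept outside a diagnosis-type section is not credited
  ev <- build_evidence("P1", mk_mentions("physician_asthma_dx", "2005-03-03",
                                         section = "unknown"))
  expect_equal(classify(ev)$granular, "none")

  base <- c("cough", "wheezing", "symptom_variability")
  dates <- c("2002-01-10", "2002-03-05", "2002-06-01")
  probable <- build_evidence("P1", mk_mentions(base, dates))
  st <- classify(probable)
  expect_equal(st$granular, "probable")
  expect_true(st$asthma)
  expect_equal(st$index_date, as.Date("2002-06-01"))

  definite <- build_evidence("P1", mk_mentions(
    c(base, "nasal_polyps"), c(dates, "2002-08-01")),
    mk_obs("eosinophil_count", "2002-09-01", 400))
  st <- classify(definite)
  expect_equal(st$granular, "definite")

  excluded <- build_evidence("P1", mk_mentions(
    c(base, "cystic_fibrosis"), c(dates, "2002-07-01")))
  st <- classify(excluded)
  expect_equal(st$granular, "excluded")
  expect_false(st$asthma)
  expect_true(is.na(st$index_date))

  cond1_only <- build_evidence("P1", mk_mentions(c("cough", "wheezing"),
                                                 dates[1:2]))
  expect_equal(classify(cond1_only)$granular, "none")

  empty <- build_evidence("P1", no_mentions())
  st <- classify(empty, as_of = as.Date("2005-01-01"))
  expect_equal(st$granular, "none")
  expect_true(is.na(st$index_date))
})

test_that("index date is the minimum over qualifying route completions", {
  # probable route completes before a later physician diagnosis
  ev <- build_evidence("P1", mk_mentions(
    c("cough", "wheezing", "symptom_variability", "physician_asthma_dx"),
    c("2002-06-01", "2003-01-01", "2002-09-01", "2004-01-01"),
    section = c("unknown", "unknown", "unknown", "diagnosis")))
  expect_equal(determine_index_date(ev), as.Date("2003-01-01"))
  expect_equal(classify(ev)$index_date, as.Date("2003-01-01"))

  # an earlier diagnosis wins over the criteria route
  ev <- build_evidence("P1", mk_mentions(
    c("cough", "wheezing", "symptom_variability", "physician_asthma_dx"),
    c("2002-06-01", "2003-01-01", "2002-09-01", "2002-08-01"),
    section = c("unknown", "unknown", "unknown", "diagnosis")))
  expect_equal(determine_index_date(ev), as.Date("2002-08-01"))

  expect_true(is.na(determine_index_date(
    build_evidence("P1", mk_mentions("cough", "2002-01-01")))))

  # as_of replay: before condition 2 is documented there is no index date
  ev <- build_evidence("P1", mk_mentions(
    c("cough", "wheezing", "symptom_variability"),
    c("2002-01-10", "2002-03-05", "2002-06-01")))
  expect_true(is.na(determine_index_date(ev, as_of = as.Date("2002-05-01"))))
  st <- classify(ev, as_of = as.Date("2002-05-01"))
  expect_equal(st$granular, "none")
})

test_that("foreign body excludes only near the candidate index date", {
  base <- mk_mentions(c("cough", "wheezing", "symptom_variability"),
                      c("2002-01-10", "2002-03-05", "2002-06-01"))
  near <- rbind(base, mk_mentions("foreign_body_near_index", "2002-09-01"))
  expect_equal(classify(build_evidence("P1", near))$granular, "excluded")
  far <- rbind(base, mk_mentions("foreign_body_near_index", "2005-09-01"))
  expect_equal(classify(build_evidence("P1", far))$granular, "probable")
})

test_that("adding evidence never revokes asthma or delays the index date", {
  extra_pool <- c("cough", "wheezing", "dyspnea", "nasal_polyps",
                  "symptom_variability", "physician_asthma_dx",
                  "bronchodilator_response", "hay_fever")
  withr::with_seed(421, {
    for (i in 1:60) {
      ev_in <- rand_evidence()
      ev_in$mentions <- ev_in$mentions[
        ev_in$mentions$concept_id != "foreign_body_near_index", , drop = FALSE]
      ev <- build_evidence("P1", ev_in$mentions, ev_in$observations,
                           birth_date = ev_in$birth_date)
      st <- classify(ev, as_of = ev_in$as_of + 400)
      if (st$granular == "excluded") next
      extra <- mk_mentions(sample(extra_pool, 1), max(ev_in$as_of) +
                             sample.int(300, 1),
                           section = "diagnosis")
      ev2 <- build_evidence("P1", rbind(ev_in$mentions, extra),
                            ev_in$observations,
                            birth_date = ev_in$birth_date)
      st2 <- classify(ev2, as_of = ev_in$as_of + 400)
      if (st$asthma) {
        expect_true(st2$asthma)
        expect_lte(as.numeric(st2$index_date), as.numeric(st$index_date))
      }
    }
  })
})

test_that("classification matches the brute-force day-by-day replay", {
  expect_engine_matches_oracle(n_cases = 300, seed = 99)
})
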