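test_that("generator config validates its fields by name", {
  expect_error(generator_config(prevalence = 1.5), "prevalence")
  expect_error(generator_config(n_patients = 0), "n_patients")
  expect_error(generator_config(notes_per_patient = c(4, 2)),
               "notes_per_patient")
  expect_error(generator_config(date_range = c("2010-01-01", "2001-01-01")),
               "date_range")
  expect_error(generator_config(p_minor_criterion = -0.1),
               "p_minor_criterion")
})

test_that("identical config and seed give byte-identical corpora", {
  cfg <- generator_config(n_patients = 30, prevalence = 0.3,
                          p_exclusion = 0.1, p_negation_distractor = 0.2,
                          p_family_distractor = 0.2, template_noise = 0.2,
                          seed = 13)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  fa <- withr::local_tempfile()
  fb <- withr::local_tempfile()
  write_corpus(a$corpus, fa)
  write_corpus(b$corpus, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
  # a different seed moves the corpus
  c <- generate_corpus(generator_config(n_patients = 30, prevalence = 0.3,
                                        p_exclusion = 0.1,
                                        p_negation_distractor = 0.2,
                                        p_family_distractor = 0.2,
                                        template_noise = 0.2, seed = 14))
  expect_false(identical(a$corpus$text, c$corpus$text))
})

test_that("degenerate prevalence yields no cases and no asthma calls", {
  synth <- generate_corpus(generator_config(n_patients = 50, prevalence = 0,
                                            seed = 7))
  expect_equal(sum(synth$truth$asthma), 0)
  st <- classify_corpus(synth$corpus, synth$observations, LEX)
  expect_equal(sum(st$asthma), 0)
})

test_that("a single noise-free definite case re-derives its own label", {
  synth <- generate_corpus(generator_config(
    n_patients = 1, prevalence = 1, p_definite_given_asthma = 1,
    template_noise = 0, seed = 1))
  expect_equal(synth$truth$granular, "definite")
  st <- classify_corpus(synth$corpus, synth$observations, LEX)
  expect_equal(st$granular, synth$truth$granular)
  expect_equal(st$index_date, synth$truth$index_date)
})

test_that("label prevalence converges to the configured rate", {
  synth <- generate_corpus(generator_config(n_patients = 400,
                                            prevalence = 0.3, seed = 23))
  p_hat <- mean(synth$truth$asthma)
  # binomial tolerance: 4 standard errors around 0.3
  expect_lt(abs(p_hat - 0.3), 4 * sqrt(0.3 * 0.7 / 400))
})

test_that("ground-truth labels are self-consistent under the PAC rules", {
  synth <- generate_corpus(generator_config(
    n_patients = 120, prevalence = 0.35, p_exclusion = 0.1, seed = 19))
  st <- classify_corpus(synth$corpus, synth$observations, LEX)
  rates <- match_rate(st, synth$truth)
  expect_equal(rates$label, 1.0)
  expect_equal(rates$index, 1.0)
})

test_that("negating every canonical sentence drives prevalence to zero", {
  synth <- generate_corpus(generator_config(
    n_patients = 60, prevalence = 0.4, p_definite_given_asthma = 0.6,
    p_exclusion = 0.05, seed = 3))
  expect_gt(sum(synth$truth$asthma), 0)
  pert <- perturb_negate_all(synth)
  st <- classify_corpus(pert$corpus, pert$observations, LEX)
  expect_equal(sum(st$asthma), 0)
  expect_equal(sum(pert$truth$asthma), 0)
  # idempotent rewrite
  pert2 <- perturb_negate_all(pert)
  expect_identical(pert2$corpus$text, pert$corpus$text)
  expect_identical(pert2$truth, pert$truth)
})

test_that("negated template counterparts never leave affirmed evidence", {
  tpl <- asthmapac:::pac_templates()
  sentences <- c(tpl$negated, asthmapac:::pac_negation_distractors())
  m <- extract_mentions(mk_corpus(sentences,
                                  note_dates = "2003-01-01"), LEX)
  affirmed <- m[m$assertion == "affirmed" & m$experiencer == "patient", ]
  expect_equal(nrow(affirmed), 0)
  # family distractors may affirm, but never about the patient
  fam <- extract_mentions(mk_corpus(asthmapac:::pac_family_distractors()),
                          LEX)
  expect_true(all(fam$experiencer == "other"))
})

test_that("every affirmed template instantiates exactly its own concept", {
  tpl <- asthmapac:::pac_templates()
  for (j in seq_len(nrow(tpl))) {
    m <- extract_mentions(mk_corpus(tpl$affirmed[j]), LEX)
    expect_true(tpl$concept[j] %in% m$concept_id,
                info = tpl$affirmed[j])
    m_aff <- m[m$assertion == "affirmed" & m$experiencer == "patient", ]
    expect_equal(m_aff$concept_id, tpl$concept[j], info = tpl$affirmed[j])
  }
  excl <- asthmapac:::pac_exclusion_sentences()
  for (k in names(excl)) {
    m <- extract_mentions(mk_corpus(excl[[k]]), LEX)
    expect_true(k %in% m$concept_id[m$assertion == "affirmed"], info = k)
  }
})

test_that("write_synthetic emits files the readers round-trip", {
  synth <- generate_corpus(generator_config(n_patients = 10,
                                            prevalence = 0.5, seed = 2))
  dir <- withr::local_tempdir()
  write_synthetic(synth, dir)
  corpus <- read_corpus(file.path(dir, "corpus.jsonl"))
  expect_equal(nrow(corpus), nrow(synth$corpus))
  obs <- read_observations(file.path(dir, "observations.csv"))
  expect_equal(nrow(obs), nrow(synth$observations))
  truth <- read_labels(file.path(dir, "truth.csv"))
  expect_equal(truth$asthma, synth$truth$asthma)
})
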