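test_that("section segmentation recognizes headers and tiles the note", {
  s <- segment_sections("DIAGNOSIS:\nAsthma.", LEX)
  expect_equal(s$label, "diagnosis")
  expect_equal(c(s$start, s$end), c(0, 18))

  txt <- "Patient seen in clinic, doing well without complaints today."
  s <- segment_sections(txt, LEX)
  expect_equal(s$label, "unknown")
  expect_equal(c(s$start, s$end), c(0, nchar(txt)))

  txt <- "FAMILY HISTORY:\nasthma in mother.\nIMPRESSION:\nstable."
  s <- segment_sections(txt, LEX)
  expect_equal(s$label, c("family_history", "impression_assessment"))
  expect_equal(s$start[2], s$end[1])          # no overlap, no gap
  expect_equal(s$end[2], nchar(txt))

  # preamble before the first header is labeled unknown
  s <- segment_sections("Routine visit.\nPLAN:\nContinue meds.", LEX)
  expect_equal(s$label, c("unknown", "plan"))
})

test_that("sentence splitting honors terminators, newlines, and guards", {
  sp <- split_sentences("Denies wheezing. No cough.", LEX)
  expect_equal(nrow(sp), 2)
  expect_equal(sp$start[1], 0)
  expect_equal(sp$end[2], nchar("Denies wheezing. No cough."))

  expect_equal(nrow(split_sentences("", LEX)), 0)
  expect_equal(nrow(split_sentences("One line\nTwo line", LEX)), 2)

  # abbreviation guard list is configurable
  txt <- "FEV1 65% pred. improved."
  expect_equal(nrow(split_sentences(txt, LEX)), 2)
  lex2 <- LEX
  lex2$abbreviations <- c(LEX$abbreviations, "pred.")
  expect_equal(nrow(split_sentences(txt, lex2)), 1)

  expect_equal(nrow(split_sentences("Seen by Dr. Smith today.", LEX)), 1)
  expect_equal(nrow(split_sentences("IgG was 1.8 mg/mL today.", LEX)), 1)
})

test_that("sentence spans tile their input", {
  for (txt in c("Denies wheezing. No cough.", "a.\n\nb.", "no terminator",
                "Trailing spaces.   ", "One. Two! Three?")) {
    sp <- split_sentences(txt, LEX)
    expect_equal(sp$start[1], 0)
    expect_equal(sp$end[nrow(sp)], nchar(txt))
    if (nrow(sp) > 1) {
      expect_equal(sp$start[-1], sp$end[-nrow(sp)])
    }
  }
})

test_that("assertion scope rule handles negation, termination, and family", {
  s <- "Denies cough and wheezing."
  pos <- regexpr("wheezing", s) - 1L
  ae <- assert_mention(s, pos, pos + 8L, LEX)
  expect_equal(ae$assertion, "negated")
  expect_equal(ae$experiencer, "patient")

  # 'but' terminates the negation scope before the concept
  s <- "No cough, but wheezing on exam."
  pos <- regexpr("wheezing on exam", s) - 1L
  ae <- assert_mention(s, pos, pos + 16L, LEX)
  expect_equal(ae$assertion, "affirmed")

  s <- "Mother has asthma."
  pos <- regexpr("asthma", s) - 1L
  ae <- assert_mention(s, pos, pos + 6L, LEX)
  expect_equal(ae$assertion, "affirmed")
  expect_equal(ae$experiencer, "other")

  s <- "Return if wheezing recurs."
  pos <- regexpr("wheezing", s) - 1L
  expect_equal(assert_mention(s, pos, pos + 8L, LEX)$assertion,
               "hypothetical")

  # multiword trigger and window limit
  s <- "Negative for wheezing."
  pos <- regexpr("wheezing", s) - 1L
  expect_equal(assert_mention(s, pos, pos + 8L, LEX)$assertion, "negated")
  s <- "No change in sleep or appetite or energy or wheezing."
  pos <- regexpr("wheezing", s) - 1L
  expect_equal(assert_mention(s, pos, pos + 8L, LEX)$assertion, "affirmed")

  # a family_history section label alone flips the experiencer
  expect_equal(assert_mention("Hay fever.", 0, 9, LEX,
                              section_label = "family_history")$experiencer,
               "other")
})

test_that("extract_mentions asserts, attributes, and consumes longest match", {
  m <- extract_mentions(mk_corpus("Patient had wheezing overnight."), LEX)
  expect_equal(m$concept_id, "wheezing")
  expect_equal(m$assertion, "affirmed")
  expect_equal(m$experiencer, "patient")

  m <- extract_mentions(mk_corpus("denied wheezing"), LEX)
  expect_equal(m$assertion, "negated")

  m <- extract_mentions(mk_corpus("no family history of asthma"), LEX)
  expect_equal(m$experiencer[m$concept_id == "physician_asthma_dx"], "other")

  expect_equal(nrow(extract_mentions(mk_corpus("Routine follow-up visit."),
                                     LEX)), 0)

  # the long nocturnal phrase consumes its embedded cough/wheeze words
  m <- extract_mentions(
    mk_corpus("Sleep disturbance by nocturnal cough and wheeze."), LEX)
  expect_equal(m$concept_id, "nocturnal_cough_wheeze")

  lex_empty <- LEX
  lex_empty$concepts <- list()
  lex_empty$regex <- list()
  expect_error(extract_mentions(mk_corpus("wheezing"), lex_empty),
               "empty lexicon")
})

test_that("prefixing 'Denies' flips every affirmed mention to negated", {
  sentences <- c("Wheezing at night.", "Coughing daily.",
                 "Nasal polyps seen.", "Hay fever in spring.",
                 "Dyspnea on exertion.")
  for (s in sentences) {
    base <- extract_mentions(mk_corpus(s), LEX)
    flipped <- extract_mentions(mk_corpus(paste("Denies", tolower(s))), LEX)
    expect_equal(nrow(flipped), nrow(base))
    expect_setequal(flipped$concept_id, base$concept_id)
    expect_true(all(base$assertion == "affirmed"))
    expect_true(all(flipped$assertion == "negated"))
  }
})

test_that("extraction is deterministic and offsets stay within bounds", {
  synth <- generate_corpus(generator_config(
    n_patients = 15, prevalence = 0.4, p_family_distractor = 0.3,
    p_negation_distractor = 0.3, template_noise = 0.3, seed = 5))
  m1 <- extract_mentions(synth$corpus, LEX)
  m2 <- extract_mentions(synth$corpus, LEX)
  expect_identical(m1, m2)
  nc <- nchar(synth$corpus$text)
  names(nc) <- synth$corpus$note_id
  expect_true(all(m1$start >= 0))
  expect_true(all(m1$end <= nc[m1$note_id]))
  expect_true(all(m1$end > m1$start))
  # the matched text is what the offsets address
  expect_equal(
    m1$text,
    substr(synth$corpus$text[match(m1$note_id, synth$corpus$note_id)],
           m1$start + 1, m1$end))
})

test_that("concatenating two notes unions their mentions at shifted offsets", {
  t1 <- "Patient reports wheezing at night."
  t2 <- "Frequent coughing episodes this month."
  m1 <- extract_mentions(mk_corpus(t1), LEX)
  m2 <- extract_mentions(mk_corpus(t2), LEX)
  mc <- extract_mentions(mk_corpus(paste(t1, t2, sep = "\n")), LEX)
  expect_equal(nrow(mc), nrow(m1) + nrow(m2))
  expect_equal(mc$concept_id, c(m1$concept_id, m2$concept_id))
  expect_equal(mc$start, c(m1$start, m2$start + nchar(t1) + 1L))
})
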