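# Shared fixtures: a cached lexicon and small constructors for corpora,
# mention tables, and observation tables built in code.

LEX <- load_lexicon()

mk_corpus <- function(texts, patient_ids = "P1", note_dates = "2003-01-01",
                      birth_dates = as.Date(NA), note_ids = NULL) {
  n <- length(texts)
  if (is.null(note_ids)) note_ids <- sprintf("N%02d", seq_len(n))
  df <- data.frame(patient_id = rep_len(patient_ids, n),
                   note_id = note_ids,
                   note_date = rep_len(as.Date(note_dates), n),
                   provider_type = NA_character_,
                   birth_date = rep_len(as.Date(birth_dates), n),
                   text = texts,
                   stringsAsFactors = FALSE)
  df$sections <- rep(list(NULL), n)
  class(df) <- c("pac_corpus", "data.frame")
  df
}

mk_mentions <- function(concepts, dates, assertion = "affirmed",
                        experiencer = "patient",
                        section = "history_present_illness",
                        patient_id = "P1") {
  n <- length(concepts)
  data.frame(patient_id = rep_len(patient_id, n),
             note_id = sprintf("N%02d", seq_len(n)),
             note_date = rep_len(as.Date(dates), n),
             concept_id = concepts,
             start = 0L, end = 1L, text = concepts,
             section_label = rep_len(section, n),
             assertion = rep_len(assertion, n),
             experiencer = rep_len(experiencer, n),
             stringsAsFactors = FALSE)
}

no_mentions <- function() asthmapac:::empty_mentions()
no_obs <- function() asthmapac:::empty_observations()

mk_obs <- function(kind, date, value, patient_id = "P1") {
  n <- max(length(kind), length(date), length(value))
  value <- rep_len(as.character(value), n)
  data.frame(patient_id = rep_len(patient_id, n),
             obs_date = rep_len(as.Date(date), n),
             kind = rep_len(kind, n),
             value = value,
             value_num = suppressWarnings(as.numeric(value)),
             stringsAsFactors = FALSE)
}

match_rate <- function(pred, truth) {
  mg <- merge(pred, truth, by = "patient_id", suffixes = c(".pred", ".truth"))
  list(
    label = mean(mg$granular.pred == mg$granular.truth),
    index = mean((is.na(mg$index_date.pred) & is.na(mg$index_date.truth)) |
                   (!is.na(mg$index_date.pred) & !is.na(mg$index_date.truth) &
                      mg$index_date.pred == mg$index_date.truth)),
    merged = mg
  )
}
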