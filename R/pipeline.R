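#' Classify every patient in a corpus
#'
#' End-to-end pipeline: extracts concept mentions from all notes
#' ([extract_mentions()]), builds each patient's cumulative evidence record
#' ([build_evidence()]), and classifies PAC status with index date
#' ([classify()]). The cohort is defined by the corpus; observations for
#' patients without notes are ignored.
#'
#' @param corpus A `pac_corpus` data frame.
#' @param observations Structured observations (may be empty).
#' @param lexicon A `pac_lexicon`.
#' @param config A `pac_config`.
#' @param as_of Classification date; defaults to the end of the corpus
#'   (latest note or observation date).
#' @param trail Attach the per-patient evidence audit trail as attribute
#'   `"trail"` (data frame with `patient_id`, `item`, `date`, `source`)?
#' @return A data frame with one row per patient: `patient_id`, `granular`,
#'   `asthma`, `index_date`.
#' @export
classify_corpus <- function(corpus, observations = empty_observations(),
                            lexicon = load_lexicon(), config = pac_config(),
                            as_of = NULL, trail = FALSE) {
  patients <- sort(unique(corpus$patient_id))
  if (!length(patients)) {
    return(data.frame(patient_id = character(), granular = character(),
                      asthma = logical(), index_date = as.Date(character()),
                      stringsAsFactors = FALSE))
  }
  mentions <- extract_mentions(corpus, lexicon, config)
  if (is.null(as_of)) {
    as_of <- max(c(corpus$note_date, observations$obs_date))
  }
  as_of <- as.Date(as_of)

  men_split <- split(mentions, factor(mentions$patient_id, levels = patients))
  obs_split <- split(observations,
                     factor(observations$patient_id, levels = patients))
  rows <- vector("list", length(patients))
  trails <- if (trail) vector("list", length(patients)) else NULL
  for (k in seq_along(patients)) {
    pid <- patients[k]
    notes_p <- corpus[corpus$patient_id == pid, , drop = FALSE]
    bd <- notes_p$birth_date[!is.na(notes_p$birth_date)]
    ev <- build_evidence(pid,
                         mentions = men_split[[pid]] %||% empty_mentions(),
                         observations = obs_split[[pid]] %||%
                           empty_observations(),
                         birth_date = if (length(bd)) bd[1] else na_date(),
                         config = config)
    st <- classify(ev, as_of = as_of, config = config)
    rows[[k]] <- data.frame(patient_id = st$patient_id,
                            granular = st$granular, asthma = st$asthma,
                            index_date = st$index_date,
                            stringsAsFactors = FALSE)
    if (trail && nrow(ev$trail)) {
      trails[[k]] <- cbind(patient_id = pid, ev$trail)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (trail) {
    trails <- trails[!vapply(trails, is.null, logical(1))]
    attr(out, "trail") <- if (length(trails)) do.call(rbind, trails) else
      data.frame(patient_id = character(), item = character(),
                 date = as.Date(character()), source = character(),
                 stringsAsFactors = FALSE)
  }
  out
}

#' Replay classification at each historical date
#'
#' Re-evaluates PAC status at every distinct evidence date in the corpus
#' (evidence is built once per patient; only the `as_of` cutoff moves),
#' reporting the cumulative asthma count and each patient's index date once
#' reached — the incident-case view of the cohort.
#'
#' @inheritParams classify_corpus
#' @param dates Candidate `as_of` dates; defaults to all distinct note and
#'   observation dates.
#' @return A data frame with one row per (`as_of`, patient) at which the
#'   patient is classified as having asthma, plus attribute `"summary"`
#'   (data frame of `as_of`, `n_asthma`).
#' @export
replay_index <- function(corpus, observations = empty_observations(),
                         lexicon = load_lexicon(), config = pac_config(),
                         dates = NULL) {
  patients <- sort(unique(corpus$patient_id))
  mentions <- extract_mentions(corpus, lexicon, config)
  men_split <- split(mentions, factor(mentions$patient_id, levels = patients))
  obs_split <- split(observations,
                     factor(observations$patient_id, levels = patients))
  evs <- lapply(seq_along(patients), function(k) {
    pid <- patients[k]
    notes_p <- corpus[corpus$patient_id == pid, , drop = FALSE]
    bd <- notes_p$birth_date[!is.na(notes_p$birth_date)]
    build_evidence(pid, men_split[[pid]] %||% empty_mentions(),
                   obs_split[[pid]] %||% empty_observations(),
                   birth_date = if (length(bd)) bd[1] else na_date(),
                   config = config)
  })
  if (is.null(dates)) {
    dates <- sort(unique(c(corpus$note_date, observations$obs_date)))
  }
  rows <- list(); summary <- list()
  for (d in as.list(as.Date(dates))) {
    statuses <- lapply(evs, classify, as_of = d, config = config)
    pos <- statuses[vapply(statuses, `[[`, logical(1), "asthma")]
    summary[[length(summary) + 1L]] <- data.frame(as_of = d,
                                                  n_asthma = length(pos))
    for (st in pos) {
      rows[[length(rows) + 1L]] <- data.frame(
        as_of = d, patient_id = st$patient_id, granular = st$granular,
        index_date = st$index_date, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(as_of = as.Date(character()), patient_id = character(),
               granular = character(), index_date = as.Date(character()),
               stringsAsFactors = FALSE)
  attr(out, "summary") <- do.call(rbind, summary)
  out
}
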