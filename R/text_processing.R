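#' Segment a note into labeled sections
#'
#' Line-anchored header detection against the lexicon's section-header
#' dictionary (e.g. `HISTORY OF PRESENT ILLNESS:`, `FAMILY HISTORY:`,
#' `DIAGNOSIS:`). A recognized header opens a section that runs to the next
#' header; any text before the first header (or a headerless note) is labeled
#' `unknown`. Spans are 0-based half-open character offsets that tile the
#' document without overlap.
#'
#' @param text Note text (single string).
#' @param lexicon A `pac_lexicon`; only its `sections` dictionary is used.
#' @return A data frame with columns `label`, `start`, `end`.
#' @examples
#' lex <- load_lexicon()
#' segment_sections("FAMILY HISTORY:\nasthma in mother.\nIMPRESSION:\nstable.",
#'                  lex)
#' @export
segment_sections <- function(text, lexicon = load_lexicon()) {
  n <- nchar(text)
  if (n == 0) {
    return(data.frame(label = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  # line start offsets (0-based)
  nl <- gregexpr("\n", text, fixed = TRUE)[[1]]
  line_starts <- if (nl[1] == -1) 0L else c(0L, as.integer(nl))
  starts <- integer(0)
  labels <- character(0)
  for (s in line_starts) {
    line_end <- nl[nl > s]
    line_end <- if (length(line_end)) min(line_end) - 1L else n
    line <- substr(text, s + 1L, line_end)
    m <- regmatches(line, regexec("^\\s*([A-Za-z][A-Za-z /]*?)\\s*:", line))[[1]]
    if (length(m) == 2) {
      canon <- lexicon$section_lookup[tolower(trimws(m[2]))]
      if (!is.na(canon)) {
        starts <- c(starts, s)
        labels <- c(labels, unname(canon))
      }
    }
  }
  if (!length(starts)) {
    return(data.frame(label = "unknown", start = 0L, end = n,
                      stringsAsFactors = FALSE))
  }
  if (starts[1] > 0) {
    starts <- c(0L, starts)
    labels <- c("unknown", labels)
  }
  data.frame(label = labels, start = starts,
             end = c(starts[-1], n), stringsAsFactors = FALSE)
}

#' Split text into sentence spans
#'
#' Deterministic rule-based splitting on sentence terminators (`.`, `!`, `?`)
#' and newlines. A period is not a boundary when the preceding token (with
#' its period) is on the abbreviation guard list, or when it sits between two
#' digits. Returned spans are 0-based half-open and tile the input;
#' whitespace-only fragments are merged into the preceding sentence.
#'
#' @param text Text of one section.
#' @param lexicon A `pac_lexicon`; only its `abbreviations` list is used.
#' @return A data frame with columns `start`, `end`. Zero rows for empty
#'   input.
#' @export
split_sentences <- function(text, lexicon = load_lexicon()) {
  n <- nchar(text)
  if (n == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  term <- gregexpr("[.!?\n]", text)[[1]]
  bounds <- integer(0)
  if (term[1] != -1) {
    for (t in as.integer(term)) { # t is 1-based position of the terminator
      ch <- substr(text, t, t)
      if (ch == ".") {
        if (t > 1 && t < n &&
            grepl("[0-9]", substr(text, t - 1, t - 1)) &&
            grepl("[0-9]", substr(text, t + 1, t + 1))) next
        ctx <- substr(text, max(1, t - 12), t)
        tok <- regmatches(ctx, regexpr("[A-Za-z.]+\\.$", ctx))
        if (length(tok) && tolower(tok) %in% lexicon$abbreviations) next
      }
      bounds <- c(bounds, t) # 0-based half-open end == 1-based position
    }
  }
  bounds <- unique(c(bounds[bounds < n], n))
  starts <- c(0L, bounds[-length(bounds)])
  spans <- data.frame(start = as.integer(starts), end = as.integer(bounds))
  # merge whitespace-only fragments into the previous sentence
  keep <- logical(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    frag <- substr(text, spans$start[i] + 1L, spans$end[i])
    keep[i] <- grepl("[^[:space:]]", frag)
  }
  if (!any(keep)) return(data.frame(start = integer(), end = integer()))
  out <- spans[keep, , drop = FALSE]
  # re-tile: each kept sentence absorbs following dropped fragments
  out$end <- c(out$start[-1], n)
  out$start[1] <- 0L
  rownames(out) <- NULL
  out
}

#' Resolve assertion and experiencer for a concept mention
#'
#' NegEx-style scope rule: a negation trigger (`denies`, `denied`, `no`,
#' `not`, `without`, `negative for`) within `window` tokens preceding the
#' concept, with no intervening scope terminator (`but`, `however`,
#' `except`), yields `negated`; hypothetical triggers (`if`, `should`,
#' `return if`) in the same window yield `hypothetical`. A family trigger
#' anywhere in the sentence (`mother`, `father`, `family history`, ...) or a
#' `family_history` section label yields experiencer `other`; otherwise the
#' mention is attributed to the patient.
#'
#' @param sentence Sentence text containing the concept.
#' @param start,end 0-based half-open character offsets of the concept within
#'   `sentence`.
#' @param lexicon A `pac_lexicon` (trigger lists).
#' @param section_label Canonical section label of the sentence.
#' @param window Token window (default 5).
#' @return A list with elements `assertion` (`affirmed`/`negated`/
#'   `hypothetical`) and `experiencer` (`patient`/`other`).
#' @examples
#' lex <- load_lexicon()
#' assert_mention("Denies cough and wheezing.", 17, 25, lex)
#' assert_mention("No cough, but wheezing on exam.", 14, 30, lex)
#' @export
assert_mention <- function(sentence, start, end, lexicon = load_lexicon(),
                           section_label = "unknown", window = 5) {
  stopifnot(start >= 0, end <= nchar(sentence), end > start)
  toks <- gregexpr("[A-Za-z0-9'-]+", sentence)[[1]]
  words <- character(0)
  if (toks[1] != -1) {
    lens <- attr(toks, "match.length")
    pre <- toks + lens - 1L <= start # 1-based token end <= 0-based concept start
    words <- tolower(regmatches(sentence, list(toks))[[1]])
    pre_words <- words[pre]
  } else {
    pre_words <- character(0)
  }

  trig <- lexicon$triggers
  scan_window <- function(triggers) {
    uni <- triggers[!grepl(" ", triggers)]
    bi <- triggers[grepl(" ", triggers)]
    np <- length(pre_words)
    for (k in seq_len(min(window, np))) {
      w <- pre_words[np - k + 1L]
      if (w %in% trig$scope_terminators) return(FALSE)
      if (w %in% uni) return(TRUE)
      if (np - k >= 1L && length(bi) &&
          paste(pre_words[np - k], w) %in% bi) {
        return(TRUE)
      }
    }
    FALSE
  }

  assertion <- if (scan_window(trig$negation)) {
    "negated"
  } else if (scan_window(trig$hypothetical)) {
    "hypothetical"
  } else {
    "affirmed"
  }

  fam_uni <- trig$family[!grepl(" ", trig$family)]
  fam_multi <- trig$family[grepl(" ", trig$family)]
  family <- identical(section_label, "family_history") ||
    any(words %in% fam_uni) ||
    any(vapply(fam_multi, function(p) grepl(p, tolower(sentence),
                                            fixed = TRUE), logical(1)))
  list(assertion = assertion,
       experiencer = if (family) "other" else "patient")
}

#' Extract PAC concept mentions from notes
#'
#' Dictionary lookup over every note in a corpus: case-insensitive
#' longest-match-per-position scanning against the lexicon (a longer surface
#' form starting at the same or an earlier position consumes the text it
#' covers, so `nocturnal cough and wheeze` is one nocturnal-symptoms mention,
#' not three), followed by section attribution, sentence location, and
#' assertion/experiencer resolution via [assert_mention()]. Notes without
#' precomputed sections are segmented with [segment_sections()] first.
#'
#' @param corpus A `pac_corpus` data frame (one or more notes).
#' @param lexicon A `pac_lexicon`.
#' @param config A `pac_config` (token window for assertion).
#' @return A data frame of mentions with columns `patient_id`, `note_id`,
#'   `note_date`, `concept_id`, `start`, `end` (0-based half-open offsets in
#'   the note), `text`, `section_label`, `assertion`, `experiencer`.
#' @export
extract_mentions <- function(corpus, lexicon = load_lexicon(),
                             config = pac_config()) {
  if (length(lexicon$concepts) == 0) stop("empty lexicon", call. = FALSE)
  out <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    out[[i]] <- extract_note_mentions(
      text = corpus$text[i],
      patient_id = corpus$patient_id[i],
      note_id = corpus$note_id[i],
      note_date = corpus$note_date[i],
      sections = corpus$sections[[i]],
      lexicon = lexicon,
      window = config$negation_window
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_mentions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_mentions <- function() {
  data.frame(patient_id = character(), note_id = character(),
             note_date = as.Date(character()), concept_id = character(),
             start = integer(), end = integer(), text = character(),
             section_label = character(), assertion = character(),
             experiencer = character(), stringsAsFactors = FALSE)
}

extract_note_mentions <- function(text, patient_id, note_id, note_date,
                                  sections, lexicon, window) {
  if (!nzchar(text)) return(NULL)
  if (is.null(sections) || nrow(sections) == 0) {
    sections <- segment_sections(text, lexicon)
  }
  # gather raw matches across all concepts
  starts <- integer(0); ends <- integer(0); concepts <- character(0)
  for (cid in names(lexicon$regex)) {
    m <- gregexpr(lexicon$regex[[cid]], text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    starts <- c(starts, as.integer(m) - 1L)
    ends <- c(ends, as.integer(m) - 1L + as.integer(len))
    concepts <- c(concepts, rep(cid, length(m)))
  }
  if (!length(starts)) return(NULL)
  # greedy longest-match-per-position scan
  ord <- order(starts, -(ends - starts))
  starts <- starts[ord]; ends <- ends[ord]; concepts <- concepts[ord]
  keep <- logical(length(starts))
  pos <- -1L
  for (j in seq_along(starts)) {
    if (starts[j] >= pos) {
      keep[j] <- TRUE
      pos <- ends[j]
    }
  }
  starts <- starts[keep]; ends <- ends[keep]; concepts <- concepts[keep]

  sent_cache <- vector("list", nrow(sections))
  rows <- vector("list", length(starts))
  for (j in seq_along(starts)) {
    si <- findInterval(starts[j], sections$start)
    sec <- sections[si, ]
    if (is.null(sent_cache[[si]])) {
      stext <- substr(text, sec$start + 1L, sec$end)
      sp <- split_sentences(stext, lexicon)
      sp$start <- sp$start + sec$start
      sp$end <- sp$end + sec$start
      sent_cache[[si]] <- sp
    }
    sp <- sent_cache[[si]]
    if (nrow(sp) == 0) next
    ki <- max(1L, findInterval(starts[j], sp$start))
    sent_start <- sp$start[ki]; sent_end <- sp$end[ki]
    sentence <- substr(text, sent_start + 1L, sent_end)
    ae <- assert_mention(sentence,
                         start = starts[j] - sent_start,
                         end = min(ends[j], sent_end) - sent_start,
                         lexicon = lexicon,
                         section_label = sec$label,
                         window = window)
    rows[[j]] <- data.frame(
      patient_id = patient_id, note_id = note_id, note_date = note_date,
      concept_id = concepts[j], start = starts[j], end = ends[j],
      text = substr(text, starts[j] + 1L, ends[j]),
      section_label = sec$label,
      assertion = ae$assertion, experiencer = ae$experiencer,
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
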