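#' Read a clinical note corpus (JSONL)
#'
#' One JSON object per line with fields `patient_id`, `note_id`, `note_date`
#' (ISO-8601), `text`, and optionally `provider_type`, `birth_date`, and
#' `sections` (list of objects with `label`, `start`, `end`; character offsets
#' are 0-based half-open). Records missing a required field raise an error
#' naming the line and field; duplicate (`patient_id`, `note_id`) pairs are
#' rejected. The result is independent of input line order.
#'
#' @param path Path to a JSONL note corpus.
#' @return A `pac_corpus` data frame, one row per note, sorted by
#'   (`patient_id`, `note_date`, `note_id`), with a `sections` list column
#'   (`NULL` where sectioning is deferred to [segment_sections()]).
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_corpus())

  required <- c("patient_id", "note_id", "note_date", "text")
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) stop(sprintf("line %d: malformed JSON (%s)",
                                       i, conditionMessage(e)), call. = FALSE))
    for (f in required) {
      if (is.null(rec[[f]]) || (is.character(rec[[f]]) && f != "text" &&
                                !nzchar(rec[[f]]))) {
        stop(sprintf("line %d: missing required field '%s'", i, f),
             call. = FALSE)
      }
    }
    d <- suppressWarnings(as.Date(as.character(rec$note_date)))
    if (is.na(d)) {
      stop(sprintf("line %d: invalid note_date '%s'", i, rec$note_date),
           call. = FALSE)
    }
    bd <- if (!is.null(rec$birth_date)) {
      suppressWarnings(as.Date(as.character(rec$birth_date)))
    } else na_date()
    sections <- NULL
    if (!is.null(rec$sections) && length(rec$sections)) {
      sec <- as.data.frame(rec$sections, stringsAsFactors = FALSE)
      validate_sections(sec, nchar(rec$text), where = sprintf("line %d", i))
      sections <- sec
    }
    recs[[i]] <- list(patient_id = as.character(rec$patient_id),
                      note_id = as.character(rec$note_id),
                      note_date = d,
                      provider_type = as.character(rec$provider_type %||% NA),
                      birth_date = bd,
                      text = as.character(rec$text),
                      sections = sections)
  }
  corpus <- data.frame(
    patient_id = vapply(recs, `[[`, character(1), "patient_id"),
    note_id = vapply(recs, `[[`, character(1), "note_id"),
    note_date = as.Date(vapply(recs, function(r) as.numeric(r$note_date),
                               numeric(1)), origin = "1970-01-01"),
    provider_type = vapply(recs, `[[`, character(1), "provider_type"),
    birth_date = as.Date(vapply(recs, function(r) as.numeric(r$birth_date),
                                numeric(1)), origin = "1970-01-01"),
    text = vapply(recs, `[[`, character(1), "text"),
    stringsAsFactors = FALSE
  )
  corpus$sections <- lapply(recs, `[[`, "sections")
  key <- paste(corpus$patient_id, corpus$note_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (patient_id, note_id): ",
         gsub("\r", "/", dup), call. = FALSE)
  }
  corpus <- corpus[order(corpus$patient_id, corpus$note_date, corpus$note_id), ]
  rownames(corpus) <- NULL
  class(corpus) <- c("pac_corpus", "data.frame")
  corpus
}

empty_corpus <- function() {
  corpus <- data.frame(patient_id = character(), note_id = character(),
                       note_date = as.Date(character()),
                       provider_type = character(),
                       birth_date = as.Date(character()),
                       text = character(), stringsAsFactors = FALSE)
  corpus$sections <- list()
  class(corpus) <- c("pac_corpus", "data.frame")
  corpus
}

validate_sections <- function(sec, n, where) {
  need <- c("label", "start", "end")
  if (!all(need %in% names(sec))) {
    stop(where, ": sections need label/start/end", call. = FALSE)
  }
  if (nrow(sec) == 0) return(invisible(sec))
  if (is.unsorted(sec$start, strictly = FALSE) ||
      any(sec$end <= sec$start) || any(sec$start < 0) || any(sec$end > n) ||
      any(utils::head(sec$end, -1) > utils::tail(sec$start, -1))) {
    stop(where, ": section spans must be ordered, non-overlapping, within ",
         "[0, nchar(text))", call. = FALSE)
  }
  invisible(sec)
}

#' Write a note corpus as JSONL
#'
#' Inverse of [read_corpus()]; round-trips losslessly.
#'
#' @param corpus A `pac_corpus` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    rec <- list(patient_id = corpus$patient_id[i],
                note_id = corpus$note_id[i],
                note_date = format(corpus$note_date[i]))
    if (!is.na(corpus$provider_type[i])) {
      rec$provider_type <- corpus$provider_type[i]
    }
    if (!is.na(corpus$birth_date[i])) {
      rec$birth_date <- format(corpus$birth_date[i])
    }
    if (!is.null(corpus$sections[[i]])) rec$sections <- corpus$sections[[i]]
    rec$text <- corpus$text[i]
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# observation kinds and their value classes
OBS_NUMERIC_KINDS <- c("eosinophil_count", "igg", "fev1_pct_pred",
                       "fvc_pct_pred", "fev1_post_bd_pct_pred",
                       "fev1_bd_improvement", "methacholine_fev1_decline")
OBS_PCT_PRED_KINDS <- c("fev1_pct_pred", "fvc_pct_pred",
                        "fev1_post_bd_pct_pred")
OBS_CATEGORICAL_KINDS <- list(
  smoking_status = c("never", "current", "former", "unknown"),
  diffusion_capacity = c("normal", "diminished")
)
OBS_KINDS <- c(OBS_NUMERIC_KINDS, names(OBS_CATEGORICAL_KINDS), "serum_ige")

#' Read a structured-observation table (CSV)
#'
#' Columns `patient_id`, `obs_date`, `kind`, `value`. Numeric kinds
#' (eosinophil counts in cells/uL, IgG in mg/mL, spirometry as percent
#' predicted, bronchodilator improvement and methacholine decline in percent)
#' are parsed to numbers; `smoking_status` and `diffusion_capacity` are
#' categorical; `serum_ige` accepts either an `elevated`/`normal` flag or a
#' numeric level in kU/L.
#'
#' @param path Path to a CSV file.
#' @return A data frame with columns `patient_id`, `obs_date` (`Date`),
#'   `kind`, `value` (character as read), `value_num` (numeric or `NA`).
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) {
    stop("observations file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("patient_id", "obs_date", "kind", "value")
  if (!all(need %in% names(df))) {
    stop("observations header must name ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) return(empty_observations())
  df$obs_date <- suppressWarnings(as.Date(df$obs_date))
  if (anyNA(df$obs_date)) {
    stop("row ", which(is.na(df$obs_date))[1], ": invalid obs_date",
         call. = FALSE)
  }
  bad <- !(df$kind %in% OBS_KINDS)
  if (any(bad)) {
    stop("row ", which(bad)[1], ": unknown observation kind '",
         df$kind[bad][1], "'", call. = FALSE)
  }
  df$value_num <- NA_real_
  for (i in seq_len(nrow(df))) {
    kind <- df$kind[i]
    val <- trimws(df$value[i])
    if (kind %in% OBS_NUMERIC_KINDS) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) {
        stop("row ", i, ": non-numeric value '", val, "' for kind ", kind,
             call. = FALSE)
      }
      if (!is.finite(num) || num < 0) {
        stop("row ", i, ": value for ", kind, " must be finite and >= 0",
             call. = FALSE)
      }
      if (kind %in% OBS_PCT_PRED_KINDS && (num <= 0 || num > 200)) {
        stop("row ", i, ": percent-predicted value out of (0, 200]",
             call. = FALSE)
      }
      df$value_num[i] <- num
    } else if (kind %in% names(OBS_CATEGORICAL_KINDS)) {
      lv <- OBS_CATEGORICAL_KINDS[[kind]]
      if (!(tolower(val) %in% lv)) {
        stop("row ", i, ": value for ", kind, " must be one of ",
             paste(lv, collapse = "/"), call. = FALSE)
      }
      df$value[i] <- tolower(val)
    } else { # serum_ige: flag or numeric level
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) {
        if (!is.finite(num) || num < 0) {
          stop("row ", i, ": serum_ige level must be finite and >= 0",
               call. = FALSE)
        }
        df$value_num[i] <- num
      } else if (!(tolower(val) %in% c("elevated", "normal"))) {
        stop("row ", i, ": serum_ige must be numeric or elevated/normal",
             call. = FALSE)
      } else {
        df$value[i] <- tolower(val)
      }
    }
  }
  df[, c("patient_id", "obs_date", "kind", "value", "value_num")]
}

empty_observations <- function() {
  data.frame(patient_id = character(), obs_date = as.Date(character()),
             kind = character(), value = character(),
             value_num = numeric(), stringsAsFactors = FALSE)
}

#' Write a structured-observation table (CSV)
#' @param observations Data frame as returned by [read_observations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  out <- data.frame(patient_id = observations$patient_id,
                    obs_date = format(observations$obs_date),
                    kind = observations$kind,
                    value = observations$value,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a patient status table (CSV)
#'
#' One row per patient with the granular PAC class
#' (definite/probable/none/excluded), the binary asthma flag, and the index
#' date (empty when absent). [read_status_table()] round-trips losslessly.
#'
#' @param statuses Data frame with columns `patient_id`, `granular`, `asthma`,
#'   `index_date`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_status_table <- function(statuses, path) {
  if (anyDuplicated(statuses$patient_id)) {
    stop("duplicate patient_id in status table: ",
         statuses$patient_id[duplicated(statuses$patient_id)][1],
         call. = FALSE)
  }
  out <- data.frame(
    patient_id = statuses$patient_id,
    granular = statuses$granular,
    asthma = statuses$asthma,
    index_date = ifelse(is.na(statuses$index_date), "",
                        format(statuses$index_date)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a patient status table written by [write_status_table()]
#' @param path Path to the CSV file.
#' @return A data frame with `patient_id`, `granular`, `asthma` (logical),
#'   `index_date` (`Date`, `NA` when absent).
#' @export
read_status_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("patient_id", "granular", "asthma", "index_date")
  if (!all(need %in% names(df))) {
    stop("status table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    patient_id = df$patient_id,
    granular = df$granular,
    asthma = if (nrow(df)) parse_flag(df$asthma) else logical(),
    index_date = as.Date(ifelse(nzchar(df$index_date), df$index_date, NA)),
    stringsAsFactors = FALSE
  )
}

#' Read a reference-standard label table (CSV)
#'
#' Requires `patient_id` and a binary `asthma` column; `granular` and
#' `index_date` columns are carried through when present.
#'
#' @param path Path to the CSV file.
#' @return A data frame with at least `patient_id` and logical `asthma`.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("patient_id", "asthma") %in% names(df))) {
    stop("label table must have columns patient_id, asthma", call. = FALSE)
  }
  out <- data.frame(patient_id = df$patient_id,
                    asthma = if (nrow(df)) parse_flag(df$asthma) else logical(),
                    stringsAsFactors = FALSE)
  if ("granular" %in% names(df)) out$granular <- df$granular
  if ("index_date" %in% names(df)) {
    out$index_date <- as.Date(ifelse(nzchar(df$index_date), df$index_date, NA))
  }
  out
}
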