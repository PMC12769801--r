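CONCEPT_EXCLUSIONS <- c("fev1_lt50_consistent_or_low_dlco",
                        "foreign_body_near_index",
                        "hypogammaglobulinemia_or_immunodeficiency",
                        "wheeze_only_anesthesia_meds",
                        "bullous_emphysema_or_fibrosis",
                        "pizz_a1at", "cystic_fibrosis",
                        "other_major_chest_disease")

MINOR_CRITERIA <- c("nocturnal_symptoms", "nonsmoker_14plus", "nasal_polyps",
                    "eosinophilia_gt300", "atopy_test_positive",
                    "atopy_history", "pft_criterion",
                    "bronchodilator_response")

#' Build a patient's cumulative PAC evidence record
#'
#' Maps asserted concept mentions and structured observations onto the PAC
#' components, dating each by the first day on which the patient's cumulative
#' documented evidence satisfies it. Condition 1 (repeated respiratory
#' symptoms) combines primary concepts across notes: cough with wheezing
#' and/or dyspnea, or cough and/or dyspnea plus wheezing at examination.
#' Condition 2 is substantial symptom variability or symptom-free periods of
#' weeks. The eight minor criteria and the eight exclusion conditions are
#' dated from concepts and observations (eosinophils strictly above the
#' 300 cells/uL threshold; the spirometry/methacholine rule via
#' [eval_pft_criterion()]; nonsmoker status at age 14 or older; IgG below
#' 2.0 mg/mL; and so on). Only affirmed mentions attributed to the patient
#' are credited, and a physician asthma diagnosis is credited only from the
#' configured diagnosis-type sections.
#'
#' @param patient_id Patient identifier.
#' @param mentions Mention data frame from [extract_mentions()], already
#'   restricted to this patient (a foreign `patient_id` is an error).
#' @param observations Structured observations for this patient (may be
#'   empty).
#' @param birth_date Birth date (`NA` permitted; the age condition of the
#'   nonsmoker criterion is then assumed met, appropriate for adult corpora).
#' @param config A `pac_config`.
#' @return An object of class `pac_evidence`: first-satisfaction dates for
#'   the physician diagnosis, conditions 1 and 2, each minor criterion, and
#'   each exclusion, plus an audit trail data frame (`item`, `date`,
#'   `source`) with one row per credited component.
#' @export
build_evidence <- function(patient_id, mentions,
                           observations = empty_observations(),
                           birth_date = na_date(),
                           config = pac_config()) {
  if (nrow(mentions) && any(mentions$patient_id != patient_id)) {
    stop("mentions contain foreign patient_id: ",
         paste(setdiff(unique(mentions$patient_id), patient_id),
               collapse = ", "), call. = FALSE)
  }
  if (nrow(observations) && any(observations$patient_id != patient_id)) {
    stop("observations contain foreign patient_id", call. = FALSE)
  }
  men <- mentions[mentions$assertion == "affirmed" &
                    mentions$experiencer == "patient", , drop = FALSE]
  obs <- observations

  trail <- list()
  log_item <- function(item, date, source) {
    if (!is.na(date)) {
      trail[[length(trail) + 1L]] <<- data.frame(
        item = item, date = date, source = source, stringsAsFactors = FALSE)
    }
  }

  # first date (and source) per concept
  first_concept <- function(cid, sections = NULL) {
    rows <- men[men$concept_id == cid, , drop = FALSE]
    if (!is.null(sections)) {
      rows <- rows[rows$section_label %in% sections, , drop = FALSE]
    }
    if (!nrow(rows)) return(list(date = na_date(), source = NA_character_))
    k <- which.min(rows$note_date)
    list(date = rows$note_date[k],
         source = sprintf("%s[%d,%d)", rows$note_id[k], rows$start[k],
                          rows$end[k]))
  }
  fdate <- function(cid, sections = NULL) first_concept(cid, sections)$date

  dx <- first_concept("physician_asthma_dx", config$dx_sections)
  log_item("physician_dx", dx$date, dx$source)

  # condition 1: secondary-concept combination, cumulative across notes
  cough <- fdate("cough"); whz <- fdate("wheezing")
  dysp <- fdate("dyspnea"); woe <- fdate("wheeze_on_exam")
  route_a <- date_max_all(cough, date_min_any(whz, dysp))
  route_b <- date_max_all(date_min_any(cough, dysp), woe)
  cond1 <- date_min_any(route_a, route_b)
  if (!is.na(cond1) && config$min_episodes > 1) {
    symptom_dates <- sort(unique(men$note_date[
      men$concept_id %in% c("cough", "wheezing", "dyspnea", "wheeze_on_exam")]))
    if (length(symptom_dates) < config$min_episodes) {
      cond1 <- na_date()
    } else {
      cond1 <- max(cond1, symptom_dates[config$min_episodes])
    }
  }
  log_item("cond1", cond1, "symptom combination")

  cond2 <- date_min_any(fdate("symptom_variability"),
                        fdate("symptom_free_weeks"))
  log_item("cond2", cond2, "symptom variability / symptom-free periods")

  obs_first <- function(kind, pred) {
    rows <- obs[obs$kind == kind, , drop = FALSE]
    if (!nrow(rows)) return(na_date())
    ok <- pred(rows)
    if (!any(ok)) return(na_date())
    min(rows$obs_date[ok])
  }

  minors <- stats::setNames(rep(na_date(), length(MINOR_CRITERIA)),
                            MINOR_CRITERIA)
  minors["nocturnal_symptoms"] <- fdate("nocturnal_cough_wheeze")
  minors["nonsmoker_14plus"] <- nonsmoker_first_date(obs, birth_date, config)
  minors["nasal_polyps"] <- fdate("nasal_polyps")
  minors["eosinophilia_gt300"] <- obs_first(
    "eosinophil_count", function(r) r$value_num > config$eosinophil_threshold)
  ige_date <- obs_first("serum_ige", function(r) {
    flag <- !is.na(r$value) & r$value == "elevated" & is.na(r$value_num)
    if (!is.null(config$ige_threshold)) {
      flag | (!is.na(r$value_num) & r$value_num >= config$ige_threshold)
    } else flag
  })
  minors["atopy_test_positive"] <- date_min_any(fdate("atopy_test_positive"),
                                                ige_date)
  minors["atopy_history"] <- date_min_any(fdate("hay_fever"),
                                          fdate("infantile_eczema"),
                                          fdate("antigen_triggered_symptoms"))
  minors["pft_criterion"] <- eval_pft_criterion(obs, config)
  minors["bronchodilator_response"] <- date_min_any(
    fdate("bronchodilator_response"),
    obs_first("fev1_bd_improvement",
              function(r) r$value_num >= config$bd_improvement_threshold))
  for (m in MINOR_CRITERIA) log_item(m, minors[[m]], "minor criterion")

  exclusions <- stats::setNames(rep(na_date(), length(CONCEPT_EXCLUSIONS)),
                                CONCEPT_EXCLUSIONS)
  for (ex in CONCEPT_EXCLUSIONS) exclusions[ex] <- fdate(ex)
  exclusions["fev1_lt50_consistent_or_low_dlco"] <- date_min_any(
    exclusions["fev1_lt50_consistent_or_low_dlco"],
    obs_first("diffusion_capacity", function(r) r$value == "diminished"),
    fev1_consistently_low_date(obs, config))
  exclusions["hypogammaglobulinemia_or_immunodeficiency"] <- date_min_any(
    exclusions["hypogammaglobulinemia_or_immunodeficiency"],
    obs_first("igg", function(r) r$value_num < config$igg_threshold))
  for (ex in setdiff(CONCEPT_EXCLUSIONS, "foreign_body_near_index")) {
    log_item(paste0("exclusion:", ex), exclusions[[ex]], "exclusion evidence")
  }
  fb_rows <- men[men$concept_id == "foreign_body_near_index", , drop = FALSE]
  foreign_body_dates <- sort(unique(fb_rows$note_date))

  all_dates <- c(men$note_date, obs$obs_date)
  all_dates <- all_dates[!is.na(all_dates)]

  structure(
    list(patient_id = patient_id,
         birth_date = birth_date,
         physician_dx_date = dx$date,
         cond1_date = cond1,
         cond2_date = cond2,
         minor_dates = minors,
         exclusion_dates = exclusions,
         foreign_body_dates = foreign_body_dates,
         date_range = if (length(all_dates)) range(all_dates) else
           c(na_date(), na_date()),
         trail = if (length(trail)) do.call(rbind, trail) else
           data.frame(item = character(), date = as.Date(character()),
                      source = character(), stringsAsFactors = FALSE)),
    class = "pac_evidence"
  )
}

# earliest date at which "latest documented smoking status is never (or
# former, if admitted) and age >= minimum" first holds
nonsmoker_first_date <- function(obs, birth_date, config) {
  rows <- obs[obs$kind == "smoking_status", , drop = FALSE]
  if (!nrow(rows)) return(na_date())
  rows <- rows[order(rows$obs_date), , drop = FALSE]
  ok_status <- c("never", if (config$admit_former_smoker) "former")
  age_ok_from <- if (is.na(birth_date)) na_date() else
    add_years(birth_date, config$nonsmoker_min_age)
  candidates <- sort(unique(c(rows$obs_date,
                              if (!is.na(age_ok_from)) age_ok_from)))
  for (d in as.list(candidates)) {
    if (!is.na(age_ok_from) && d < age_ok_from) next
    prior <- rows[rows$obs_date <= d, , drop = FALSE]
    if (!nrow(prior)) next
    latest <- prior$value[which.max(prior$obs_date)]
    if (latest %in% ok_status) return(d)
  }
  na_date()
}

# FEV1 consistently below the exclusion threshold: at least two FEV1
# percent-predicted measurements, all below threshold so far
fev1_consistently_low_date <- function(obs, config) {
  rows <- obs[obs$kind == "fev1_pct_pred", , drop = FALSE]
  if (nrow(rows) < 2) return(na_date())
  rows <- rows[order(rows$obs_date), , drop = FALSE]
  low <- rows$value_num < config$fev1_exclusion_pct
  for (k in 2:nrow(rows)) {
    if (all(low[1:k])) return(rows$obs_date[k])
    if (!all(low[1:k])) break
  }
  na_date()
}

#' Evaluate the pulmonary-function-test minor criterion
#'
#' Satisfied at the earliest date by which either (a) some FEV1 or FVC below
#' 70% predicted has been recorded and another test shows improvement of at
#' least 20% reaching an FEV1 above 70% predicted, or (b) a methacholine
#' challenge shows an FEV1 decline of 20% or more. Both the 20% improvement
#' and the 20% decline are inclusive boundaries. Improvement evidence is
#' accepted either as an explicit improvement observation
#' (`fev1_bd_improvement` at or above 20 together with a same-day FEV1 above
#' 70% predicted) or as a pair of spirometries whose relative change meets
#' the rule.
#'
#' @param observations Structured observations for one patient.
#' @param config A `pac_config`.
#' @return The earliest satisfaction `Date`, or `NA` if never satisfied.
#' @export
eval_pft_criterion <- function(observations, config = pac_config()) {
  obs <- observations
  if (!nrow(obs)) return(na_date())

  lows <- obs[obs$kind %in% c("fev1_pct_pred", "fvc_pct_pred") &
                obs$value_num < config$pft_low_pct, , drop = FALSE]
  first_low <- if (nrow(lows)) min(lows$obs_date) else na_date()

  improvement_dates <- as.Date(character())
  imp <- obs[obs$kind == "fev1_bd_improvement" &
               obs$value_num >= config$pft_improvement_pct, , drop = FALSE]
  if (nrow(imp)) {
    post <- obs[obs$kind %in% c("fev1_post_bd_pct_pred", "fev1_pct_pred") &
                  obs$value_num > config$pft_post_pct, , drop = FALSE]
    ok <- imp$obs_date %in% post$obs_date
    improvement_dates <- c(improvement_dates, imp$obs_date[ok])
  }
  # pairwise spirometry route: a later FEV1 above the post threshold that
  # improves on some earlier low measurement by >= the improvement threshold
  f2 <- obs[obs$kind == "fev1_pct_pred" &
              obs$value_num > config$pft_post_pct, , drop = FALSE]
  if (nrow(f2) && nrow(lows)) {
    for (k in seq_len(nrow(f2))) {
      earlier <- lows[lows$obs_date < f2$obs_date[k], , drop = FALSE]
      if (nrow(earlier) &&
          any((f2$value_num[k] - earlier$value_num) / earlier$value_num *
                100 >= config$pft_improvement_pct)) {
        improvement_dates <- c(improvement_dates, f2$obs_date[k])
      }
    }
  }
  route_a <- na_date()
  if (!is.na(first_low) && length(improvement_dates)) {
    qual <- improvement_dates[improvement_dates >= first_low]
    if (length(qual)) route_a <- min(qual)
  }

  meth <- obs[obs$kind == "methacholine_fev1_decline" &
                obs$value_num >= config$methacholine_decline_pct, ,
              drop = FALSE]
  route_b <- if (nrow(meth)) min(meth$obs_date) else na_date()

  date_min_any(route_a, route_b)
}

#' Classify a patient's asthma status under PAC
#'
#' Applies the PAC decision rule to cumulative evidence as of a given date:
#' any exclusion condition present on or before `as_of` makes the patient
#' `excluded`; otherwise *definite* asthma requires a physician diagnosis of
#' asthma or conditions 1 and 2 plus at least two minor criteria, *probable*
#' asthma requires conditions 1 and 2 only, and anything else is `none`. A
#' tracheobronchial foreign body is an exclusion only when it falls within
#' the configured window around the candidate index date. The index date —
#' the first date PAC is met — is attached when the patient has asthma
#' (definite or probable).
#'
#' @param evidence A `pac_evidence` from [build_evidence()].
#' @param as_of Classification date; defaults to the end of the patient's
#'   evidence timeline.
#' @param config A `pac_config`.
#' @return A list of class `pac_status`: `patient_id`, `granular`
#'   (`definite`/`probable`/`none`/`excluded`), `asthma` (logical), and
#'   `index_date` (`Date`, `NA` unless asthma).
#' @export
classify <- function(evidence, as_of = NULL, config = pac_config()) {
  stopifnot(inherits(evidence, "pac_evidence"))
  if (is.null(as_of)) as_of <- evidence$date_range[2]
  as_of <- as.Date(as_of)
  le <- function(d) !is.na(d) & d <= as_of

  index_date <- determine_index_date(evidence, as_of = as_of, config = config)

  excl <- evidence$exclusion_dates
  excluded <- any(le(excl[setdiff(names(excl), "foreign_body_near_index")]))
  fb <- evidence$foreign_body_dates
  fb <- fb[!is.na(fb) & fb <= as_of]
  if (length(fb) && !is.na(index_date) &&
      any(abs(as.numeric(fb - index_date)) <=
            config$foreign_body_window_days)) {
    excluded <- TRUE
  }

  if (excluded) {
    granular <- "excluded"
  } else {
    n_minor <- sum(le(evidence$minor_dates))
    has12 <- le(evidence$cond1_date) && le(evidence$cond2_date)
    granular <- if (le(evidence$physician_dx_date) ||
                    (has12 && n_minor >= 2)) {
      "definite"
    } else if (has12) {
      "probable"
    } else {
      "none"
    }
  }
  asthma <- granular %in% c("definite", "probable")
  structure(list(patient_id = evidence$patient_id,
                 granular = granular,
                 asthma = asthma,
                 index_date = if (asthma) index_date else na_date()),
            class = "pac_status")
}

#' Determine the PAC index date
#'
#' The index date is the first calendar date at which cumulative evidence
#' meets PAC by any qualifying route: the physician-diagnosis route completes
#' at the first diagnosis date; the probable route completes when the later
#' of conditions 1 and 2 is first satisfied; the definite-by-criteria route
#' completes when conditions 1 and 2 and the second-earliest minor criterion
#' are all satisfied. The minimum over qualifying routes is returned, `NA` if
#' no route qualifies. Exclusions do not enter this computation (the
#' classifier suppresses the date for excluded patients).
#'
#' @param evidence A `pac_evidence`.
#' @param as_of Only evidence on or before this date is considered; defaults
#'   to the end of the patient's timeline.
#' @param config A `pac_config`.
#' @return A `Date`, or `NA`.
#' @export
determine_index_date <- function(evidence, as_of = NULL,
                                 config = pac_config()) {
  stopifnot(inherits(evidence, "pac_evidence"))
  if (is.null(as_of)) as_of <- evidence$date_range[2]
  as_of <- as.Date(as_of)
  clip <- function(d) {
    d[!is.na(d) & d > as_of] <- NA
    d
  }
  dx <- clip(evidence$physician_dx_date)
  c1 <- clip(evidence$cond1_date)
  c2 <- clip(evidence$cond2_date)
  minors <- sort(clip(evidence$minor_dates), na.last = NA)
  probable_route <- date_max_all(c1, c2)
  definite_route <- if (length(minors) >= 2) {
    date_max_all(c1, c2, minors[2])
  } else {
    na_date()
  }
  date_min_any(dx, probable_route, definite_route)
}

#' @export
print.pac_status <- function(x, ...) {
  cat(sprintf("<pac_status> %s: %s (asthma=%s, index=%s)\n",
              x$patient_id, x$granular, x$asthma,
              if (is.na(x$index_date)) "-" else format(x$index_date)))
  invisible(x)
}

#' @export
print.pac_evidence <- function(x, ...) {
  cat("<pac_evidence>", x$patient_id, "\n")
  fmt <- function(d) if (is.na(d)) "-" else format(d)
  cat("  physician dx:", fmt(x$physician_dx_date), "\n")
  cat("  condition 1: ", fmt(x$cond1_date), "\n")
  cat("  condition 2: ", fmt(x$cond2_date), "\n")
  met <- x$minor_dates[!is.na(x$minor_dates)]
  cat("  minor criteria met:", if (length(met))
    paste(sprintf("%s (%s)", names(met), format(met)), collapse = ", ")
    else "none", "\n")
  exc <- x$exclusion_dates[!is.na(x$exclusion_dates)]
  cat("  exclusions:", if (length(exc))
    paste(names(exc), collapse = ", ") else "none", "\n")
  invisible(x)
}
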