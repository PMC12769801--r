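#' Configuration for the synthetic corpus generator
#'
#' Defines the study conditions a generated corpus emulates: cohort size,
#' asthma prevalence (the validation cohort this design mirrors ran at about
#' 5%), the split of cases into definite versus probable, the per-patient
#' note timeline, distractor rates (negated symptoms, family-history
#' mentions), the exclusion rate, per-minor-criterion documentation
#' probabilities, and filler-noise rate. The same config and seed always
#' produce a byte-identical corpus.
#'
#' @param n_patients Number of patients (>= 1).
#' @param prevalence Probability a patient is a true asthma case.
#' @param p_definite_given_asthma Probability a case is definite (vs
#'   probable).
#' @param notes_per_patient Integer range `c(min, max)` of notes per patient.
#' @param date_range Character or `Date` vector `c(start, end)` bounding all
#'   note and observation dates.
#' @param p_negation_distractor Per-note probability of a negated-symptom
#'   distractor sentence.
#' @param p_family_distractor Per-note probability of a family-history
#'   distractor (in running text or a dedicated family-history section).
#' @param p_exclusion Probability a non-case patient carries full case
#'   evidence plus one exclusion condition (ground truth `excluded`).
#' @param p_minor_criterion Scalar or named vector of per-criterion
#'   documentation probabilities for definite cases (at least two minor
#'   criteria are always planted for a criteria-route definite case).
#' @param template_noise Per-note probability of a non-canonical filler
#'   sentence.
#' @param seed Integer seed; all sampling derives from it.
#' @return A validated list of class `pac_generator_config`.
#' @export
generator_config <- function(n_patients = 500,
                             prevalence = 0.05,
                             p_definite_given_asthma = 0.6,
                             notes_per_patient = c(2, 4),
                             date_range = c("2001-01-01", "2010-12-31"),
                             p_negation_distractor = 0,
                             p_family_distractor = 0,
                             p_exclusion = 0,
                             p_minor_criterion = 0.3,
                             template_noise = 0,
                             seed = 42) {
  cfg <- list(n_patients = n_patients, prevalence = prevalence,
              p_definite_given_asthma = p_definite_given_asthma,
              notes_per_patient = notes_per_patient,
              date_range = as.Date(date_range),
              p_negation_distractor = p_negation_distractor,
              p_family_distractor = p_family_distractor,
              p_exclusion = p_exclusion,
              p_minor_criterion = p_minor_criterion,
              template_noise = template_noise,
              seed = seed)
  if (!is_scalar_number(n_patients) || n_patients < 1) {
    stop("generator_config: 'n_patients' must be >= 1", call. = FALSE)
  }
  for (f in c("prevalence", "p_definite_given_asthma",
              "p_negation_distractor", "p_family_distractor", "p_exclusion",
              "template_noise")) {
    v <- cfg[[f]]
    if (!is_scalar_number(v) || v < 0 || v > 1) {
      stop("generator_config: '", f, "' must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (length(notes_per_patient) != 2 ||
      any(notes_per_patient < 1) ||
      notes_per_patient[1] > notes_per_patient[2]) {
    stop("generator_config: 'notes_per_patient' must be c(min, max), min >= 1",
         call. = FALSE)
  }
  if (anyNA(cfg$date_range) || cfg$date_range[1] >= cfg$date_range[2]) {
    stop("generator_config: 'date_range' must be two ordered dates",
         call. = FALSE)
  }
  pm <- p_minor_criterion
  if (length(pm) == 1 && is.null(names(pm))) {
    pm <- stats::setNames(rep(pm, length(MINOR_CRITERIA)), MINOR_CRITERIA)
  }
  if (!all(MINOR_CRITERIA %in% names(pm)) || any(pm < 0) || any(pm > 1)) {
    stop("generator_config: 'p_minor_criterion' must be a probability or a ",
         "fully named vector over the eight minor criteria", call. = FALSE)
  }
  cfg$p_minor_criterion <- pm[MINOR_CRITERIA]
  if (!is_scalar_number(seed)) {
    stop("generator_config: 'seed' must be a single number", call. = FALSE)
  }
  structure(cfg, class = "pac_generator_config")
}

sample_one <- function(x) x[sample.int(length(x), 1L)]

#' Generate a labeled synthetic patient corpus
#'
#' Builds a corpus of dated clinical notes, structured observations, and a
#' ground-truth label table whose labels and index dates are derivable from
#' the planted evidence by the PAC rules (self-consistency by construction).
#' Cases receive note timelines whose sentences instantiate canonical
#' templates for the two major conditions (and, for definite cases, either a
#' diagnosis-section physician-diagnosis sentence or at least two minor
#' criteria); threshold-bearing criteria are planted as observations
#' straddling their boundaries (eosinophil counts both at/below and above
#' 300 cells/uL, spirometry pairs); non-cases receive only distractors
#' (negated symptoms, family-history mentions, filler); excluded patients
#' receive full case evidence plus one exclusion condition. The planted
#' index date is the date the last required PAC component first appears.
#'
#' @param config A `pac_generator_config`.
#' @return A list of class `pac_synthetic` with elements `corpus`
#'   (`pac_corpus` data frame), `observations`, `truth` (columns
#'   `patient_id`, `granular`, `asthma`, `index_date`, `planted`), and
#'   `config`.
#' @examples
#' synth <- generate_corpus(generator_config(n_patients = 5, seed = 7))
#' synth$truth
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "pac_generator_config"))
  with_local_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  tpl <- pac_templates()
  d0 <- config$date_range[1]
  span <- as.integer(config$date_range[2] - d0)
  notes <- list(); obs <- list(); truth <- list()

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", i)
    birth <- d0 - round(stats::runif(1, 25, 85) * 365.25)
    n_notes <- sample_one(seq(config$notes_per_patient[1],
                              config$notes_per_patient[2]))
    note_dates <- sort(d0 + sample.int(span + 1L, n_notes,
                                       replace = TRUE) - 1L)

    is_case <- stats::runif(1) < config$prevalence
    is_excluded <- !is_case && stats::runif(1) < config$p_exclusion
    is_definite <- is_case &&
      stats::runif(1) < config$p_definite_given_asthma
    dx_route <- is_definite && stats::runif(1) < 0.5

    plan <- plan_patient(pid = pid, birth = birth, note_dates = note_dates,
                         is_case = is_case, is_excluded = is_excluded,
                         is_definite = is_definite, dx_route = dx_route,
                         config = config, tpl = tpl)

    truth_row <- derive_truth(pid, plan)
    target <- if (is_excluded) "excluded" else if (!is_case) "none" else
      if (is_definite) "definite" else "probable"
    if (truth_row$granular != target) {
      stop("internal: planted evidence for ", pid, " derives '",
           truth_row$granular, "' but target was '", target, "'")
    }
    truth[[i]] <- truth_row
    notes[[i]] <- materialize_notes(pid, birth, note_dates, plan, config)
    obs[[i]] <- plan$obs
  }

  corpus <- do.call(rbind, notes)
  corpus$sections <- rep(list(NULL), nrow(corpus))
  corpus <- corpus[order(corpus$patient_id, corpus$note_date,
                         corpus$note_id), ]
  rownames(corpus) <- NULL
  class(corpus) <- c("pac_corpus", "data.frame")
  obs <- do.call(rbind, obs[!vapply(obs, is.null, logical(1))])
  if (is.null(obs)) obs <- empty_observations()
  rownames(obs) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(corpus = corpus, observations = obs, truth = truth,
                 config = config),
            class = "pac_synthetic")
}

# Decide every evidence event (sentences and observations) for one patient.
# Sentence events carry the note index and target section; observation rows
# are final. Concept events feed the analytic ground-truth derivation.
plan_patient <- function(pid, birth, note_dates, is_case, is_excluded,
                         is_definite, dx_route, config, tpl) {
  n_notes <- length(note_dates)
  sent <- list()    # (note, section, sentence)
  cev <- list()     # (concept, date) for truth
  obs_rows <- list()
  planted <- character(0)

  add_sentence <- function(note, section, sentence) {
    sent[[length(sent) + 1L]] <<- list(note = note, section = section,
                                       sentence = sentence)
  }
  add_concept <- function(concept, note,
                          section = "hpi") {
    row <- tpl[tpl$concept == concept, , drop = FALSE]
    row <- row[sample.int(nrow(row), 1L), ]
    add_sentence(note, section, row$affirmed)
    cev[[length(cev) + 1L]] <<- list(concept = concept,
                                     date = note_dates[note])
    planted <<- c(planted, concept)
  }
  add_obs <- function(kind, date, value, value_num = NA_real_) {
    obs_rows[[length(obs_rows) + 1L]] <<- data.frame(
      patient_id = pid, obs_date = date, kind = kind,
      value = as.character(value), value_num = value_num,
      stringsAsFactors = FALSE)
  }

  # smoking status documented at intake for everyone; probable cases are
  # kept off 'never' so incidental minor criteria cannot promote them
  smoking_probs <- c(never = 0.52, current = 0.12, former = 0.35,
                     unknown = 0.01)
  smoking <- sample(names(smoking_probs), 1, prob = smoking_probs)
  force_nonsmoker <- FALSE

  full_case <- is_case || is_excluded
  minors_selected <- character(0)

  if (full_case) {
    combos <- list(c("cough", "wheezing"), c("cough", "dyspnea"),
                   c("dyspnea", "wheeze_on_exam"),
                   c("cough", "wheeze_on_exam"))
    combo <- combos[[sample.int(length(combos), 1L)]]
    for (cc in combo) add_concept(cc, sample.int(n_notes, 1L))
    add_concept(sample_one(c("symptom_variability", "symptom_free_weeks")),
                sample.int(n_notes, 1L))
  }
  if (is_definite && dx_route) {
    add_concept("physician_asthma_dx", sample.int(n_notes, 1L),
                section = "diagnosis")
    if (stats::runif(1) < 0.4) {
      add_concept(sample_one(c("hay_fever", "infantile_eczema")),
                  sample.int(n_notes, 1L))
    }
  }
  if (is_definite && !dx_route) {
    draw <- stats::runif(length(MINOR_CRITERIA)) < config$p_minor_criterion
    minors_selected <- MINOR_CRITERIA[draw]
    while (length(minors_selected) < 2) {
      minors_selected <- union(minors_selected,
                               sample_one(setdiff(MINOR_CRITERIA,
                                                  minors_selected)))
    }
  } else if (is_case && stats::runif(1) < 0.4) {
    # probable cases may carry one documented minor criterion (never two);
    # atopic history is the most commonly documented one
    cand <- setdiff(MINOR_CRITERIA, c("pft_criterion", "nonsmoker_14plus"))
    w <- ifelse(cand == "atopy_history", 0.45, 0.55 / (length(cand) - 1))
    minors_selected <- sample(cand, 1, prob = w)
  }
  if (is_case && !is_definite) {
    if (smoking == "never") smoking <- sample_one(c("current", "former"))
  }

  for (m in minors_selected) {
    note <- sample.int(n_notes, 1L)
    d <- note_dates[note]
    switch(m,
      nocturnal_symptoms = add_concept("nocturnal_cough_wheeze", note),
      nonsmoker_14plus = { force_nonsmoker <- TRUE },
      nasal_polyps = add_concept("nasal_polyps", note),
      eosinophilia_gt300 = {
        v <- round(stats::runif(1, 320, 700))
        add_obs("eosinophil_count", d, v, v)
      },
      atopy_test_positive = {
        if (stats::runif(1) < 0.5) {
          add_concept("atopy_test_positive", note)
        } else {
          add_obs("serum_ige", d, "elevated")
        }
      },
      atopy_history = add_concept(sample_one(c("hay_fever",
                                               "infantile_eczema",
                                               "antigen_triggered_symptoms")),
                                  note),
      pft_criterion = {
        note2 <- sample_one(seq(note, n_notes))
        low <- round(stats::runif(1, 50, 69))
        add_obs("fev1_pct_pred", d, low, low)
        imp <- round(stats::runif(1, 20, 40))
        post <- round(stats::runif(1, 72, 95))
        add_obs("fev1_bd_improvement", note_dates[note2], imp, imp)
        add_obs("fev1_post_bd_pct_pred", note_dates[note2], post, post)
      },
      bronchodilator_response = {
        if (stats::runif(1) < 0.7) {
          add_concept("bronchodilator_response", note)
        } else {
          v <- round(stats::runif(1, 12, 18))
          add_obs("fev1_bd_improvement", d, v, v)
        }
      })
    if (m %in% c("eosinophilia_gt300", "nonsmoker_14plus", "pft_criterion") ||
        (m == "atopy_test_positive" && !("atopy_test_positive" %in% planted))) {
      planted <- c(planted, m)
    }
  }
  if (force_nonsmoker) smoking <- "never"
  add_obs("smoking_status", note_dates[1], smoking)

  exclusion_kind <- NA_character_
  if (is_excluded) {
    exclusion_kind <- sample_one(names(pac_exclusion_sentences()))
    planted <- c(planted, paste0("exclusion:", exclusion_kind))
  }

  # non-cases: partial evidence that must never complete PAC
  if (!full_case) {
    if (stats::runif(1) < 0.25) {
      add_concept(sample_one(c("cough", "wheezing", "dyspnea",
                               "wheeze_on_exam")), sample.int(n_notes, 1L))
    }
    if (stats::runif(1) < 0.15) {
      add_concept(sample_one(c("symptom_variability", "symptom_free_weeks")),
                  sample.int(n_notes, 1L))
    }
    if (stats::runif(1) < 0.12) {
      # atopic history without respiratory disease: a lone minor criterion
      add_concept(sample_one(c("hay_fever", "infantile_eczema")),
                  sample.int(n_notes, 1L))
    }
    if (stats::runif(1) < 0.3) {
      # sub-threshold eosinophils, occasionally exactly on the boundary
      v <- if (stats::runif(1) < 0.15) 300 else
        round(stats::runif(1, 80, 299))
      add_obs("eosinophil_count", sample_one(note_dates), v, v)
    }
    if (stats::runif(1) < 0.2) {
      v <- round(stats::runif(1, 75, 110))
      add_obs("fev1_pct_pred", sample_one(note_dates), v, v)
    }
  }

  list(sent = sent, cev = cev,
       obs = if (length(obs_rows)) do.call(rbind, obs_rows) else NULL,
       smoking = smoking, smoking_date = note_dates[1], birth = birth,
       note_dates = note_dates, exclusion_kind = exclusion_kind,
       planted = planted, is_excluded = is_excluded)
}

# Analytic ground truth from the planned events, mirroring the PAC rules the
# engine applies to extracted text (defaults of pac_config()).
derive_truth <- function(pid, plan) {
  cev <- plan$cev
  f <- function(concept) {
    d <- vapply(cev, function(e)
      if (e$concept == concept) as.numeric(e$date) else NA_real_, numeric(1))
    d <- d[!is.na(d)]
    if (!length(d)) na_date() else as.Date(min(d), origin = "1970-01-01")
  }
  obs <- plan$obs
  obs_min <- function(kind, pred) {
    if (is.null(obs)) return(na_date())
    rows <- obs[obs$kind == kind, , drop = FALSE]
    if (!nrow(rows)) return(na_date())
    ok <- pred(rows)
    if (!any(ok)) return(na_date())
    min(rows$obs_date[ok])
  }

  route_a <- date_max_all(f("cough"), date_min_any(f("wheezing"),
                                                   f("dyspnea")))
  route_b <- date_max_all(date_min_any(f("cough"), f("dyspnea")),
                          f("wheeze_on_exam"))
  c1 <- date_min_any(route_a, route_b)
  c2 <- date_min_any(f("symptom_variability"), f("symptom_free_weeks"))
  dx <- f("physician_asthma_dx")

  pft_low <- obs_min("fev1_pct_pred", function(r) r$value_num < 70)
  pft_imp <- na_date()
  if (!is.null(obs)) {
    imp <- obs[obs$kind == "fev1_bd_improvement" & obs$value_num >= 20, ,
               drop = FALSE]
    post <- obs[obs$kind %in% c("fev1_post_bd_pct_pred", "fev1_pct_pred") &
                  obs$value_num > 70, , drop = FALSE]
    ok <- imp$obs_date %in% post$obs_date
    if (any(ok)) pft_imp <- min(imp$obs_date[ok])
  }
  pft <- if (!is.na(pft_low) && !is.na(pft_imp) && pft_imp >= pft_low) {
    pft_imp
  } else na_date()

  minors <- c(
    nocturnal_symptoms = f("nocturnal_cough_wheeze"),
    nonsmoker_14plus = if (plan$smoking == "never") plan$smoking_date else
      na_date(),
    nasal_polyps = f("nasal_polyps"),
    eosinophilia_gt300 = obs_min("eosinophil_count",
                                 function(r) r$value_num > 300),
    atopy_test_positive = date_min_any(
      f("atopy_test_positive"),
      obs_min("serum_ige", function(r) r$value == "elevated" &
                is.na(r$value_num))),
    atopy_history = date_min_any(f("hay_fever"), f("infantile_eczema"),
                                 f("antigen_triggered_symptoms")),
    pft_criterion = pft,
    bronchodilator_response = date_min_any(
      f("bronchodilator_response"),
      obs_min("fev1_bd_improvement", function(r) r$value_num >= 12))
  )

  if (plan$is_excluded) {
    granular <- "excluded"
  } else {
    has12 <- !is.na(c1) && !is.na(c2)
    granular <- if (!is.na(dx) || (has12 && sum(!is.na(minors)) >= 2)) {
      "definite"
    } else if (has12) "probable" else "none"
  }
  asthma <- granular %in% c("definite", "probable")
  index <- if (asthma) date_min_any(dx, date_max_all(c1, c2)) else na_date()

  data.frame(patient_id = pid, granular = granular, asthma = asthma,
             index_date = index,
             planted = paste(unique(plan$planted), collapse = ";"),
             stringsAsFactors = FALSE)
}

materialize_notes <- function(pid, birth, note_dates, plan, config) {
  n_notes <- length(note_dates)
  hpi <- rep(list(character(0)), n_notes)
  impression <- rep(list(character(0)), n_notes)
  diagnosis <- rep(list(character(0)), n_notes)
  family <- rep(list(character(0)), n_notes)

  for (ev in plan$sent) {
    k <- ev$note
    switch(ev$section,
           hpi = hpi[[k]] <- c(hpi[[k]], ev$sentence),
           impression = impression[[k]] <- c(impression[[k]], ev$sentence),
           diagnosis = diagnosis[[k]] <- c(diagnosis[[k]], ev$sentence))
  }

  if (!is.na(plan$exclusion_kind)) {
    sent <- pac_exclusion_sentences()[[plan$exclusion_kind]]
    if (plan$exclusion_kind == "foreign_body_near_index") {
      # at or about the would-be index date: attach to the latest note that
      # carries planted evidence (the completion date of the case evidence)
      ev_dates <- vapply(plan$cev, function(e) as.numeric(e$date), numeric(1))
      target <- which(note_dates == as.Date(max(ev_dates),
                                            origin = "1970-01-01"))[1]
    } else {
      target <- sample.int(n_notes, 1L)
    }
    impression[[target]] <- c(impression[[target]], sent)
  }

  for (k in seq_len(n_notes)) {
    if (stats::runif(1) < config$p_negation_distractor) {
      hpi[[k]] <- c(hpi[[k]], sample_one(pac_negation_distractors()))
    }
    if (stats::runif(1) < config$p_family_distractor) {
      if (stats::runif(1) < 0.5) {
        hpi[[k]] <- c(hpi[[k]], sample_one(pac_family_distractors()))
      } else {
        family[[k]] <- c(family[[k]],
                         sample_one(pac_family_section_sentences()))
      }
    }
    if (stats::runif(1) < config$template_noise) {
      hpi[[k]] <- c(hpi[[k]], sample_one(pac_filler_sentences()))
    }
    if (!length(hpi[[k]]) && !length(impression[[k]]) &&
        !length(diagnosis[[k]]) && !length(family[[k]])) {
      hpi[[k]] <- sample_one(pac_filler_sentences())
    }
    if (length(hpi[[k]]) > 1) hpi[[k]] <- sample(hpi[[k]])
  }

  texts <- vapply(seq_len(n_notes), function(k) {
    blocks <- character(0)
    if (length(hpi[[k]])) {
      blocks <- c(blocks, paste0("HISTORY OF PRESENT ILLNESS:\n",
                                 paste(hpi[[k]], collapse = "\n")))
    }
    if (length(family[[k]])) {
      blocks <- c(blocks, paste0("FAMILY HISTORY:\n",
                                 paste(family[[k]], collapse = "\n")))
    }
    if (length(impression[[k]])) {
      blocks <- c(blocks, paste0("IMPRESSION:\n",
                                 paste(impression[[k]], collapse = "\n")))
    }
    if (length(diagnosis[[k]])) {
      blocks <- c(blocks, paste0("DIAGNOSIS:\n",
                                 paste(diagnosis[[k]], collapse = "\n")))
    }
    paste(blocks, collapse = "\n")
  }, character(1))

  data.frame(patient_id = pid,
             note_id = sprintf("%s-N%02d", pid, seq_len(n_notes)),
             note_date = note_dates,
             provider_type = sample(c("physician", "nurse", "pulmonology"),
                                    n_notes, replace = TRUE),
             birth_date = birth,
             text = texts,
             stringsAsFactors = FALSE)
}

#' Negate every canonical affirmed evidence sentence in a corpus
#'
#' Rewrites each affirmed generator template occurring in the note text with
#' its negated counterpart and relabels affected ground truth to `none`
#' (excluded patients keep their exclusion evidence and label). The rewrite
#' is idempotent. Running the pipeline on the perturbed corpus must yield
#' zero asthma calls — the end-to-end check that assertion handling, not
#' mere phrase spotting, drives classification.
#'
#' @param synth A `pac_synthetic` from [generate_corpus()].
#' @return A `pac_synthetic` with rewritten note text and relabeled truth.
#' @export
perturb_negate_all <- function(synth) {
  stopifnot(inherits(synth, "pac_synthetic"))
  tpl <- pac_templates()
  txt <- synth$corpus$text
  for (j in seq_len(nrow(tpl))) {
    txt <- gsub(tpl$affirmed[j], tpl$negated[j], txt, fixed = TRUE)
  }
  synth$corpus$text <- txt
  flip <- synth$truth$granular %in% c("definite", "probable")
  synth$truth$granular[flip] <- "none"
  synth$truth$asthma[flip] <- FALSE
  synth$truth$index_date[flip] <- na_date()
  synth
}

#' Write a synthetic corpus bundle to a directory
#'
#' Emits `corpus.jsonl`, `observations.csv`, and `truth.csv` in the same
#' formats [read_corpus()], [read_observations()], and [read_labels()]
#' consume.
#'
#' @param synth A `pac_synthetic`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(synth, dir) {
  stopifnot(inherits(synth, "pac_synthetic"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_corpus(synth$corpus, file.path(dir, "corpus.jsonl"))
  write_observations(synth$observations, file.path(dir, "observations.csv"))
  truth <- synth$truth
  truth$index_date <- ifelse(is.na(truth$index_date), "",
                             format(truth$index_date))
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = TRUE)
  invisible(dir)
}

#' Canonical test corpus configuration
#'
#' Loads the versioned configuration (config plus seed fully determine the
#' corpus) of the canonical synthetic validation cohort: 500 patients at 5%
#' asthma prevalence, either noise-free (`distractors = FALSE`) or with
#' negation/family-history distractors and filler sentences at rate 0.3.
#'
#' @param distractors Load the distractor variant?
#' @param path Path to the canonical config YAML (packaged default).
#' @return A `pac_generator_config`.
#' @export
canonical_corpus_config <- function(distractors = FALSE,
                                    path = system.file(
                                      "extdata",
                                      "canonical_corpus_config.yaml",
                                      package = "asthmapac",
                                      mustWork = TRUE)) {
  raw <- yaml::read_yaml(path)
  block <- raw[[if (distractors) "distractor" else "clean"]]
  do.call(generator_config, block)
}
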