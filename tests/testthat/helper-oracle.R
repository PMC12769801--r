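# Independent brute-force oracle: re-evaluates the PAC rule set from scratch
# at every candidate date (boolean cumulative state, no closed-form date
# arithmetic), used to cross-check classify()/determine_index_date().

oracle_classify <- function(mentions, observations, birth_date = as.Date(NA),
                            as_of, fb_window = 365) {
  dx_sections <- c("diagnosis", "impression_assessment", "plan")
  men_ok <- mentions[mentions$assertion == "affirmed" &
                       mentions$experiencer == "patient", , drop = FALSE]
  b14 <- if (is.na(birth_date)) as.Date(NA) else
    asthmapac:::add_years(birth_date, 14)

  state_at <- function(d) {
    men <- men_ok[men_ok$note_date <= d, , drop = FALSE]
    obs <- observations[observations$obs_date <= d, , drop = FALSE]
    has <- function(cid) cid %in% men$concept_id
    dx <- any(men$concept_id == "physician_asthma_dx" &
                men$section_label %in% dx_sections)
    c1 <- (has("cough") && (has("wheezing") || has("dyspnea"))) ||
      ((has("cough") || has("dyspnea")) && has("wheeze_on_exam"))
    c2 <- has("symptom_variability") || has("symptom_free_weeks")

    # nonsmoker: sticky — satisfied if at any earlier day the latest
    # documented status was 'never' while aged >= 14
    smoking <- obs[obs$kind == "smoking_status", , drop = FALSE]
    nonsmoker <- FALSE
    if (nrow(smoking)) {
      cand <- sort(unique(c(smoking$obs_date,
                            if (!is.na(b14) && b14 <= d) b14)))
      for (dd in as.list(cand)) {
        if (!is.na(b14) && dd < b14) next
        prior <- smoking[smoking$obs_date <= dd, , drop = FALSE]
        if (nrow(prior) &&
            prior$value[which.max(prior$obs_date)] == "never") {
          nonsmoker <- TRUE
          break
        }
      }
    }
    eos <- any(obs$kind == "eosinophil_count" & obs$value_num > 300)
    atopy_test <- has("atopy_test_positive") ||
      any(obs$kind == "serum_ige" & is.na(obs$value_num) &
            obs$value == "elevated")
    atopy_hist <- has("hay_fever") || has("infantile_eczema") ||
      has("antigen_triggered_symptoms")

    lows <- obs[obs$kind %in% c("fev1_pct_pred", "fvc_pct_pred") &
                  obs$value_num < 70, , drop = FALSE]
    pft <- any(obs$kind == "methacholine_fev1_decline" &
                 obs$value_num >= 20)
    if (!pft && nrow(lows)) {
      imp <- obs[obs$kind == "fev1_bd_improvement" & obs$value_num >= 20, ,
                 drop = FALSE]
      post <- obs[obs$kind %in% c("fev1_post_bd_pct_pred", "fev1_pct_pred") &
                    obs$value_num > 70, , drop = FALSE]
      for (dd in as.list(imp$obs_date)) {
        if (dd %in% post$obs_date && min(lows$obs_date) <= dd) pft <- TRUE
      }
      f2 <- obs[obs$kind == "fev1_pct_pred" & obs$value_num > 70, ,
                drop = FALSE]
      for (k in seq_len(nrow(f2))) {
        e <- lows[lows$obs_date < f2$obs_date[k], , drop = FALSE]
        if (nrow(e) && any((f2$value_num[k] - e$value_num) / e$value_num *
                             100 >= 20)) {
          pft <- TRUE
        }
      }
    }
    bd <- has("bronchodilator_response") ||
      any(obs$kind == "fev1_bd_improvement" & obs$value_num >= 12)
    nminor <- sum(has("nocturnal_cough_wheeze"), nonsmoker,
                  has("nasal_polyps"), eos, atopy_test, atopy_hist, pft, bd)

    fev1 <- obs[obs$kind == "fev1_pct_pred", , drop = FALSE]
    fev1 <- fev1[order(fev1$obs_date), , drop = FALSE]
    low50 <- nrow(fev1) >= 2 && all(fev1$value_num[1:2] < 50)
    excl <- has("fev1_lt50_consistent_or_low_dlco") || low50 ||
      any(obs$kind == "diffusion_capacity" & obs$value == "diminished") ||
      has("hypogammaglobulinemia_or_immunodeficiency") ||
      any(obs$kind == "igg" & obs$value_num < 2.0) ||
      has("wheeze_only_anesthesia_meds") ||
      has("bullous_emphysema_or_fibrosis") ||
      has("pizz_a1at") || has("cystic_fibrosis") ||
      has("other_major_chest_disease")
    list(dx = dx, c1 = c1, c2 = c2, nminor = nminor, excl = excl,
         pac = dx || (c1 && c2))
  }

  dates <- sort(unique(c(mentions$note_date, observations$obs_date)))
  dates <- dates[dates <= as_of]
  index <- as.Date(NA)
  for (d in as.list(dates)) {
    if (state_at(d)$pac) {
      index <- d
      break
    }
  }
  fin <- state_at(as_of)
  fb <- men_ok$note_date[men_ok$concept_id == "foreign_body_near_index"]
  fb <- fb[fb <= as_of]
  excluded <- fin$excl ||
    (length(fb) > 0 && !is.na(index) &&
       any(abs(as.numeric(fb - index)) <= fb_window))
  granular <- if (excluded) {
    "excluded"
  } else if (fin$dx || (fin$c1 && fin$c2 && fin$nminor >= 2)) {
    "definite"
  } else if (fin$c1 && fin$c2) {
    "probable"
  } else {
    "none"
  }
  asthma <- granular %in% c("definite", "probable")
  list(granular = granular, asthma = asthma,
       index_date = if (asthma) index else as.Date(NA))
}

# random small evidence set over <= 6 dates, exercising thresholds,
# exclusions, smoking-status flips, and under-14 timelines
rand_evidence <- function() {
  d0 <- as.Date("2003-01-01")
  dates <- sort(d0 + sample.int(730, sample.int(6, 1)))
  concepts_pool <- c("cough", "wheezing", "dyspnea", "wheeze_on_exam",
                     "symptom_variability", "symptom_free_weeks",
                     "nocturnal_cough_wheeze", "nasal_polyps", "hay_fever",
                     "bronchodilator_response", "atopy_test_positive",
                     "physician_asthma_dx", "cystic_fibrosis",
                     "foreign_body_near_index")
  n_men <- stats::rbinom(1, 8, 0.45)
  mentions <- no_mentions()
  if (n_men > 0) {
    cids <- sample(concepts_pool, n_men, replace = TRUE)
    mentions <- mk_mentions(
      cids,
      dates = sample(dates, n_men, replace = TRUE),
      assertion = sample(c("affirmed", "negated"), n_men, replace = TRUE,
                         prob = c(0.8, 0.2)),
      experiencer = sample(c("patient", "other"), n_men, replace = TRUE,
                           prob = c(0.9, 0.1)),
      section = "unknown")
    dx_rows <- mentions$concept_id == "physician_asthma_dx"
    mentions$section_label[dx_rows] <-
      sample(c("diagnosis", "unknown"), sum(dx_rows), replace = TRUE)
  }
  obs <- list()
  add <- function(kind, value) {
    obs[[length(obs) + 1L]] <<- mk_obs(kind, sample(dates, 1), value)
  }
  if (stats::runif(1) < 0.5) {
    for (k in seq_len(sample.int(2, 1))) {
      add("smoking_status", sample(c("never", "current", "former"), 1))
    }
  }
  if (stats::runif(1) < 0.4) add("eosinophil_count", sample(295:320, 1))
  if (stats::runif(1) < 0.3) add("serum_ige", "elevated")
  if (stats::runif(1) < 0.4) {
    for (k in seq_len(sample.int(3, 1))) {
      add("fev1_pct_pred", sample(40:95, 1))
    }
  }
  if (stats::runif(1) < 0.3) {
    d <- sample(dates, 1)
    v <- sample(10:30, 1)
    obs[[length(obs) + 1L]] <- mk_obs("fev1_bd_improvement", d, v)
    if (stats::runif(1) < 0.7) {
      obs[[length(obs) + 1L]] <- mk_obs("fev1_post_bd_pct_pred", d,
                                        sample(60:90, 1))
    }
  }
  if (stats::runif(1) < 0.2) {
    add("methacholine_fev1_decline", sample(15:25, 1))
  }
  if (stats::runif(1) < 0.15) add("igg", stats::runif(1, 1, 4))
  if (stats::runif(1) < 0.1) add("diffusion_capacity", "diminished")
  observations <- if (length(obs)) do.call(rbind, obs) else no_obs()

  birth <- if (stats::runif(1) < 0.25) {
    d0 - round(stats::runif(1, 12.5, 15.5) * 365.25) # age ~14 in-window
  } else {
    d0 - round(stats::runif(1, 20, 70) * 365.25)
  }
  list(mentions = mentions, observations = observations, birth_date = birth,
       as_of = max(dates) + sample.int(60, 1))
}

expect_engine_matches_oracle <- function(n_cases, seed) {
  withr::with_seed(seed, {
    for (i in seq_len(n_cases)) {
      ev_in <- rand_evidence()
      ev <- build_evidence("P1", ev_in$mentions, ev_in$observations,
                           birth_date = ev_in$birth_date)
      got <- classify(ev, as_of = ev_in$as_of)
      want <- oracle_classify(ev_in$mentions, ev_in$observations,
                              ev_in$birth_date, ev_in$as_of)
      ok <- identical(got$granular, want$granular) &&
        identical(got$asthma, want$asthma) &&
        ((is.na(got$index_date) && is.na(want$index_date)) ||
           (!is.na(got$index_date) && !is.na(want$index_date) &&
              got$index_date == want$index_date))
      if (!ok) {
        fail(sprintf(
          "case %d: engine (%s, index %s) vs oracle (%s, index %s)",
          i, got$granular, format(got$index_date),
          want$granular, format(want$index_date)))
        return(invisible(FALSE))
      }
    }
    succeed()
    invisible(TRUE)
  })
}
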