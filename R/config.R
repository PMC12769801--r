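#' PAC engine configuration
#'
#' Numeric thresholds and behavioral switches for the PAC rule engine. The
#' defaults encode the published criteria: blood eosinophilia strictly above
#' 300 cells/uL; spirometry with one FEV1 or FVC below 70% predicted and
#' another test with at least 20% improvement to FEV1 above 70% predicted, or
#' a methacholine challenge with a decline of 20% or more; FEV1 consistently
#' below 50% predicted (or diminished diffusion capacity) as an exclusion;
#' IgG below 2.0 mg/mL for hypogammaglobulinemia; and the nonsmoker minor
#' criterion restricted to age 14 or older.
#'
#' @param eosinophil_threshold Cells/uL; eosinophilia requires a count
#'   strictly greater than this (default 300).
#' @param pft_low_pct Percent predicted below which an FEV1/FVC counts as low
#'   (default 70, strict `<`).
#' @param pft_improvement_pct Minimum percent improvement, inclusive
#'   (default 20).
#' @param pft_post_pct Percent predicted the improved FEV1 must exceed
#'   (default 70, strict `>`).
#' @param methacholine_decline_pct Minimum percent FEV1 decline on
#'   methacholine challenge, inclusive (default 20).
#' @param fev1_exclusion_pct Percent predicted; FEV1 consistently below this
#'   is an exclusion (default 50).
#' @param igg_threshold mg/mL; IgG strictly below this is
#'   hypogammaglobulinemia (default 2.0).
#' @param ige_threshold kU/L; a numeric serum IgE at or above this counts as
#'   elevated. `NULL` (default) means only an explicit `elevated` flag counts,
#'   since the criteria name no cutoff.
#' @param nonsmoker_min_age Years; minimum age for the nonsmoker criterion
#'   (default 14).
#' @param admit_former_smoker Should a latest documented status of `former`
#'   satisfy the nonsmoker criterion? Default `FALSE` (only `never`).
#' @param bd_improvement_threshold Percent; a numeric post-bronchodilator
#'   FEV1 improvement at or above this counts as a favorable bronchodilator
#'   response when no textual evidence exists (default 12).
#' @param foreign_body_window_days Half-width in days of the window around
#'   the candidate index date within which a tracheobronchial foreign body
#'   triggers exclusion (default 365).
#' @param min_episodes Minimum number of distinct dates bearing condition-1
#'   respiratory symptom evidence (default 1).
#' @param dx_sections Canonical section labels from which a physician asthma
#'   diagnosis concept may be credited.
#' @param negation_window Token window preceding a concept scanned for
#'   negation/hypothetical triggers (default 5).
#' @return A list of class `pac_config`.
#' @export
pac_config <- function(eosinophil_threshold = 300,
                       pft_low_pct = 70,
                       pft_improvement_pct = 20,
                       pft_post_pct = 70,
                       methacholine_decline_pct = 20,
                       fev1_exclusion_pct = 50,
                       igg_threshold = 2.0,
                       ige_threshold = NULL,
                       nonsmoker_min_age = 14,
                       admit_former_smoker = FALSE,
                       bd_improvement_threshold = 12,
                       foreign_body_window_days = 365,
                       min_episodes = 1,
                       dx_sections = c("diagnosis", "impression_assessment",
                                       "plan"),
                       negation_window = 5) {
  cfg <- list(eosinophil_threshold = eosinophil_threshold,
              pft_low_pct = pft_low_pct,
              pft_improvement_pct = pft_improvement_pct,
              pft_post_pct = pft_post_pct,
              methacholine_decline_pct = methacholine_decline_pct,
              fev1_exclusion_pct = fev1_exclusion_pct,
              igg_threshold = igg_threshold,
              ige_threshold = ige_threshold,
              nonsmoker_min_age = nonsmoker_min_age,
              admit_former_smoker = isTRUE(admit_former_smoker),
              bd_improvement_threshold = bd_improvement_threshold,
              foreign_body_window_days = foreign_body_window_days,
              min_episodes = min_episodes,
              dx_sections = dx_sections,
              negation_window = negation_window)
  for (f in c("eosinophil_threshold", "pft_low_pct", "pft_improvement_pct",
              "pft_post_pct", "methacholine_decline_pct", "fev1_exclusion_pct",
              "igg_threshold", "nonsmoker_min_age", "bd_improvement_threshold",
              "foreign_body_window_days", "min_episodes", "negation_window")) {
    if (!is_scalar_number(cfg[[f]]) || cfg[[f]] < 0) {
      stop("pac_config: '", f, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  structure(cfg, class = "pac_config")
}
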