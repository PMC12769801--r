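# Canonical sentence templates used by the synthetic corpus generator.
# Each affirmed template instantiates exactly one lexicon concept (longer
# surface forms deliberately consume any embedded symptom words), and each
# has a negated counterpart whose wording places a negation trigger inside
# the assertion scope window of every surviving concept pattern. The
# affirmed -> negated mapping is what perturb_negate_all() rewrites.

pac_templates <- function() {
  tpl <- rbind(
    c("cough", "Patient reports persistent cough.",
      "Patient denies any cough."),
    c("cough", "Frequent coughing episodes this month.",
      "Denies coughing episodes this month."),
    c("wheezing", "Patient reports wheezing at night.",
      "Patient denies wheezing at night."),
    c("wheezing", "Audible wheeze noted again today.",
      "No audible wheeze today."),
    c("dyspnea", "Complains of dyspnea on exertion.",
      "No dyspnea on exertion."),
    c("dyspnea", "Reports shortness of breath climbing stairs.",
      "Denies shortness of breath."),
    c("wheeze_on_exam", "Expiratory wheezes on auscultation today.",
      "No wheezes on auscultation today."),
    c("wheeze_on_exam", "Wheezing on exam bilaterally.",
      "No wheezing on exam."),
    c("symptom_variability",
      "Substantial variability in symptoms from time to time.",
      "Not much variability in symptoms."),
    c("symptom_variability", "Symptoms wax and wane over the season.",
      "Symptoms have fully resolved."),
    c("symptom_free_weeks", "Symptom-free for several weeks at a time.",
      "Not symptom-free for several weeks."),
    c("symptom_free_weeks", "Asymptomatic for weeks at a stretch.",
      "Not asymptomatic for weeks."),
    c("nocturnal_cough_wheeze",
      "Sleep disturbance by nocturnal cough and wheeze.",
      "Denies nocturnal cough or wheeze."),
    c("nocturnal_cough_wheeze", "Awakens at night with cough and wheeze.",
      "Denies nocturnal cough or wheeze lately."),
    c("nasal_polyps", "Nasal polyps seen on rhinoscopy.",
      "No nasal polyps seen."),
    c("hay_fever", "History of hay fever since childhood.",
      "No history of hay fever."),
    c("infantile_eczema", "Infantile eczema as a child.",
      "No infantile eczema."),
    c("antigen_triggered_symptoms",
      "Cough, dyspnea, and wheezing regularly on exposure to an antigen.",
      "Denies symptoms on allergen exposure."),
    c("atopy_test_positive", "Positive wheal and flare skin tests.",
      "Skin testing unremarkable."),
    c("atopy_test_positive", "Elevated serum IgE on laboratory testing.",
      "Serum IgE within normal limits."),
    c("bronchodilator_response",
      "Favorable clinical response to bronchodilator therapy.",
      "No response to bronchodilator therapy."),
    c("bronchodilator_response", "Improved with albuterol as needed.",
      "Albuterol was of no benefit."),
    c("physician_asthma_dx", "Asthma, stable on current therapy.",
      "No evidence of asthma."),
    c("physician_asthma_dx", "Bronchial asthma.",
      "No bronchial asthma.")
  )
  data.frame(concept = tpl[, 1], affirmed = tpl[, 2], negated = tpl[, 3],
             stringsAsFactors = FALSE)
}

pac_exclusion_sentences <- function() {
  c(fev1_lt50_consistent_or_low_dlco =
      "Diminished diffusion capacity on pulmonary function testing.",
    foreign_body_near_index =
      "Tracheobronchial foreign body removed at bronchoscopy.",
    hypogammaglobulinemia_or_immunodeficiency =
      "Hypogammaglobulinemia on immune workup.",
    wheeze_only_anesthesia_meds =
      "Wheezing occurring only in response to anesthesia.",
    bullous_emphysema_or_fibrosis =
      "Bullous emphysema on chest radiograph.",
    pizz_a1at = "PiZZ alpha-1 antitrypsin phenotype.",
    cystic_fibrosis = "Cystic fibrosis, confirmed by sweat chloride.",
    other_major_chest_disease = "Bronchiectasis on chest CT.")
}

pac_family_distractors <- function() {
  c("Family history of asthma in mother.",
    "Mother has asthma and hay fever.",
    "Father had wheezing and chronic cough.",
    "Sister with infantile eczema.")
}

# sentence planted in a dedicated FAMILY HISTORY section
pac_family_section_sentences <- function() {
  c("Asthma in father.", "Hay fever in mother.", "Asthma, maternal side.")
}

pac_negation_distractors <- function() {
  c("Patient denies wheezing.",
    "No cough or dyspnea today.",
    "Denies hay fever.",
    "No nasal polyps on inspection.",
    "Denies nocturnal cough or wheeze.",
    "Not short of breath at rest.")
}

pac_filler_sentences <- function() {
  c("Patient doing well overall.",
    "Vital signs stable.",
    "Follow up in 3 months.",
    "Medication list reviewed and updated.",
    "Immunizations up to date.",
    "Diet and exercise discussed.",
    "Blood pressure well controlled.",
    "Laboratory results reviewed with patient.")
}
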