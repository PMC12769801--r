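# Default concept lexicon and context rules for PAC evidence extraction.
#
# Every concept the PAC rule engine can credit is enumerated here with its
# case-insensitive surface patterns (literal phrases; internal whitespace is
# matched flexibly). The file is user-replaceable: institutions with their
# own phrase inventories can point the pipeline at an edited copy.
concepts:
  wheezing:
    - wheezing
    - wheezes
    - wheeze
    - wheezy
    - audible wheeze
  cough:
    - coughing
    - coughs
    - coughed
    - cough
  dyspnea:
    - dyspnea
    - dyspneic
    - shortness of breath
    - short of breath
    - breathlessness
  wheeze_on_exam:
    - wheezing on exam
    - wheezing on examination
    - wheezing on lung exam
    - wheezes on auscultation
    - wheeze on auscultation
    - expiratory wheezes on exam
  symptom_variability:
    - substantial variability in symptoms
    - variability in symptoms
    - symptoms vary from time to time
    - symptoms wax and wane
    - episodic symptoms
    - intermittent symptoms
  symptom_free_weeks:
    - symptom-free for several weeks
    - symptom-free for weeks
    - symptom free for weeks
    - symptom-free intervals
    - asymptomatic for weeks
  nocturnal_cough_wheeze:
    - sleep disturbance by nocturnal cough and wheeze
    - awakens at night with cough and wheeze
    - nocturnal cough and wheeze
    - nocturnal cough or wheeze
    - nighttime cough and wheezing
    - nocturnal wheezing
  nasal_polyps:
    - nasal polyps
    - nasal polyp
    - nasal polyposis
  hay_fever:
    - hay fever
    - allergic rhinitis
    - seasonal allergic rhinitis
  infantile_eczema:
    - infantile eczema
    - eczema in infancy
    - atopic dermatitis in infancy
    - childhood eczema
  antigen_triggered_symptoms:
    - cough, dyspnea, and wheezing regularly on exposure to an antigen
    - symptoms regularly on exposure to an antigen
    - symptoms on exposure to an antigen
    - symptoms on allergen exposure
  bronchodilator_response:
    - favorable clinical response to bronchodilator
    - favorable response to bronchodilator
    - good response to bronchodilator
    - improved with albuterol
    - symptoms relieved by inhaler
    - responded well to nebulizer
  atopy_test_positive:
    - positive wheal and flare skin tests
    - positive wheal and flare
    - positive skin test
    - skin prick test positive
    - elevated serum ige
    - elevated ige
  physician_asthma_dx:
    - bronchial asthma
    - asthma
  # one concept per PAC exclusion condition
  fev1_lt50_consistent_or_low_dlco:
    - fev1 consistently below 50
    - fev1 consistently less than 50
    - diminished diffusion capacity
    - reduced diffusion capacity
    - low dlco
  foreign_body_near_index:
    - tracheobronchial foreign body
    - foreign body aspiration
    - aspirated foreign body
    - airway foreign body
  hypogammaglobulinemia_or_immunodeficiency:
    - hypogammaglobulinemia
    - immunodeficiency disorder
    - common variable immunodeficiency
    - immune deficiency
  wheeze_only_anesthesia_meds:
    - wheezing occurring only in response to anesthesia
    - wheezing only in response to anesthesia
    - wheezing only with anesthesia
    - wheezing only after medications
    - wheezing only in response to medications
  bullous_emphysema_or_fibrosis:
    - bullous emphysema
    - pulmonary fibrosis
  pizz_a1at:
    - pizz alpha-1 antitrypsin
    - pizz phenotype
    - pizz
  cystic_fibrosis:
    - cystic fibrosis
  other_major_chest_disease:
    - juvenile kyphoscoliosis
    - kyphoscoliosis
    - bronchiectasis
    - major chest disease

triggers:
  negation:
    - denies
    - denied
    - "no"
    - "not"
    - without
    - negative for
  hypothetical:
    - "if"
    - should
    - return if
  family:
    - mother
    - father
    - sibling
    - brother
    - sister
    - grandmother
    - grandfather
    - family
    - family history
  scope_terminators:
    - but
    - however
    - except

sections:
  history_present_illness:
    - history of present illness
    - hpi
    - history
  past_medical_history:
    - past medical history
    - pmh
  family_history:
    - family history
    - fh
  social_history:
    - social history
    - sh
  medications:
    - medications
    - meds
    - current medications
  allergies:
    - allergies
    - allergy
  review_of_systems:
    - review of systems
    - ros
  physical_exam:
    - physical exam
    - physical examination
    - examination
    - exam
  impression_assessment:
    - impression
    - assessment
    - impression/assessment
  diagnosis:
    - diagnosis
    - diagnoses
    - final diagnosis
    - dx
  plan:
    - plan
    - plan of care

abbreviations:
  - dr.
  - mr.
  - mrs.
  - ms.
  - vs.
  - e.g.
  - i.e.
  - etc.
  - st.
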