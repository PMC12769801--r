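# Canonical synthetic validation corpora (config + seed; the corpus itself
# is regenerated deterministically). "clean" is the noise-free
# self-consistency fixture; "distractor" adds negation/family-history
# distractors and filler at rate 0.3 for the robustness regression surface.
clean:
  n_patients: 500
  prevalence: 0.05
  p_definite_given_asthma: 0.6
  p_exclusion: 0.02
  seed: 42
distractor:
  n_patients: 500
  prevalence: 0.05
  p_definite_given_asthma: 0.6
  p_exclusion: 0.02
  p_negation_distractor: 0.3
  p_family_distractor: 0.3
  template_noise: 0.3
  seed: 42
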