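# asthmapac

Rule-based ascertainment of asthma status from free-text clinical notes,
built on the **Predetermined Asthma Criteria (PAC)** — a fixed, chart-review
rule set for retrospective asthma phenotyping that also dates incident
asthma. The package is aimed at EHR phenotyping and epidemiology groups who
need a transparent, auditable alternative to diagnosis-code ascertainment:
every positive call can be traced back to the sentence or laboratory value
that produced it.

## What it computes

A patient has **definite** asthma if a physician has made a diagnosis of
asthma, *or* if all three of the following hold; **probable** asthma if only
the first two hold:

1. history of cough with wheezing and/or dyspnea, *or* cough and/or dyspnea
   plus wheezing at examination;
2. substantial variability in symptoms over time, or symptom-free periods of
   weeks or more;
3. two or more *minor criteria*: nocturnal cough and wheeze; nonsmoker aged
   ≥ 14; nasal polyps; blood eosinophilia > 300 cells/µL; positive skin
   tests or elevated serum IgE; history of hay fever or infantile eczema or
   antigen-triggered symptoms; pulmonary function tests with one FEV₁ or FVC
   < 70 % predicted and another showing ≥ 20 % improvement to FEV₁ > 70 %
   predicted (or a methacholine challenge with ≥ 20 % FEV₁ decline); or a
   favorable response to bronchodilator therapy.

Exclusion conditions (FEV₁ consistently < 50 % predicted or diminished
diffusion capacity, tracheobronchial foreign body near the index date,
hypogammaglobulinemia with IgG < 2.0 mg/mL or other immunodeficiency,
wheezing only with anesthesia or medications, bullous emphysema or pulmonary
fibrosis, PiZZ α₁-antitrypsin, cystic fibrosis, other major chest disease)
remove a patient from the case pool. The **index date** is the first
calendar day on which the cumulative documented evidence meets PAC.

The pipeline has two components, mirroring how such systems are built:

* **Clinical text processing** — line-anchored section segmentation,
  rule-based sentence splitting, dictionary concept extraction
  (case-insensitive longest-match; the lexicon is an editable YAML file),
  and NegEx-style assertion resolution (negation and hypothetical triggers
  in a five-token scope window with scope terminators) plus experiencer
  attribution (family-history triggers and section labels).
* **Patient classification** — asserted mentions and structured
  observations (labs, spirometry, smoking status) are combined into the PAC
  conditions cumulatively over the patient timeline; classification and
  index dating follow the rules above.

Validation utilities compute the criterion-validity statistics (unweighted
Cohen's κ, agreement, sensitivity, specificity, PPV, NPV) and
construct-validity 2×2 odds ratios with Wald 95 % confidence intervals, and
a seeded synthetic-corpus generator produces labeled note corpora so the
whole pipeline is testable without any protected health information.

## Worked example

```r
library(asthmapac)

synth    <- generate_corpus(generator_config(n_patients = 8,
                                             prevalence = 0.4, seed = 101))
statuses <- classify_corpus(synth$corpus, synth$observations)
statuses
#>   patient_id granular asthma index_date
#> 1      P0001 definite   TRUE 2006-11-13
#> 2      P0002 probable   TRUE 2009-03-21
#> 3      P0003     none  FALSE       <NA>
#> 4      P0004 definite   TRUE 2002-02-25
#> ...

validate_statuses(statuses, synth$truth)$metrics
#> PAC criterion validity (n = 8 )
#>   sensitivity: 100%  specificity: 100%
#>   PPV: 100%  NPV: 100%
#>   accuracy: 100%  agreement: 1
#>   kappa: 1
```

Each row is one patient: the granular PAC class, the binary asthma flag
(definite or probable), and the index date — the day the last required
criterion component was first documented. On a published validation
confusion matrix the same metric code reproduces the printed statistics:

```r
diagnostic_metrics(confusion_matrix(tp = 89, fn = 8, fp = 9, tn = 1792))
#> PAC criterion validity (n = 1898 )
#>   sensitivity: 92%  specificity: 100%
#>   PPV: 91%  NPV: 100%
#>   accuracy: 99%  agreement: 0.99
#>   kappa: 0.91
```

(Specificity and NPV compute to 99.50 % and 99.56 %; the half-away-from-zero
display convention shows 100.)

A command-line wrapper ships at `inst/scripts/asthmapac`:

```sh
Rscript inst/scripts/asthmapac generate --out demo --n 50 --seed 7
Rscript inst/scripts/asthmapac classify --corpus demo/corpus.jsonl \
    --observations demo/observations.csv --out demo/status.csv --trail demo/trail.csv
Rscript inst/scripts/asthmapac validate --pred demo/status.csv --labels demo/truth.csv
```

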