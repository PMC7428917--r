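# tsann — time-sensitive attentive neural networks for clinical risk prediction

`tsann` predicts **asthma exacerbation risk** from longitudinal EHR visit
sequences and explains its predictions through attention weights. It is
aimed at clinical-informatics researchers who work with retrospective
case-control cohorts built from coded encounter data (diagnoses,
medications, demographics) and who need both a risk score per patient and
a ranked, time-bucketed list of contributing factors.

## The model

TSANN is a hierarchical attention network over an LSTM, made
time-sensitive by *elapsed-time embeddings*:

* **Code-level attention** inside each visit: with concept embeddings
  *C<sub>ij</sub>*,

  *u<sub>ij</sub>* = tanh(*W<sub>v</sub>C<sub>ij</sub>* + *b<sub>v</sub>*),
  &nbsp; *α<sub>ij</sub>* = softmax<sub>j</sub>(*u<sub>ij</sub>*ᵀ*u<sub>v</sub>*),
  &nbsp; *v<sub>i</sub>* = Σ<sub>j</sub> *α<sub>ij</sub>C<sub>ij</sub>*

* **Elapsed-time embedding**: the whole-day gap between visit *i* and the
  prediction date (365-bin vocabulary) indexes a learned embedding row
  concatenated to *v<sub>i</sub>* — time as a representation, not a decay
  scalar.
* **LSTM** over the visit vectors (standard sigmoid gates, configurable
  candidate activation).
* **Visit-level attention** over hidden states:
  *β<sub>i</sub>* = softmax<sub>i</sub>(tanh(*W<sub>p</sub>h<sub>i</sub>* +
  *b<sub>p</sub>*)ᵀ*u<sub>p</sub>*), *r<sub>p</sub>* = Σ *β<sub>i</sub>h<sub>i</sub>*
  (variant `TSANN_II`; `TSANN_I` uses the final hidden state instead).
* **Output**: dense layer (optional batch norm) + 2-way softmax → risk
  probability *P*.

The products *β<sub>i</sub>α<sub>ij</sub>*, normalized per patient, drive
the interpretation layer: per-patient heatmaps, cohort-level factor
rankings with month buckets ("code/N" = N months before the prediction
date), and temporal scatters of a factor's contribution across patients.

Everything around the model is included: retrospective cohort rules
(index date = first asthma diagnosis with a same-day asthma medication;
exacerbation date = primary asthma diagnosis at an ED/inpatient encounter
with same-day oral corticosteroid; 365-day case/control labeling;
training/testA/testB prediction-date modes; audited inclusion/exclusion
filters), deterministic sequence encoding, baselines (ridge logistic
regression, MLP, LSTM, attentive LSTM, time-ablated and step-time
variants), stratified 8:2 + five-fold cross-validated grid search with
best-epoch selection, rank-based AUC, paired Wilcoxon model comparison,
and a synthetic EHR generator with *planted, time-localized risk factors*
so that every stage is testable without proprietary data. Forward and
backward passes are implemented in the package and validated against
finite differences.

## Worked example

Simulate a cohort with one strong planted risk factor, build the cohort,
train the one-level model, and recover the factor:

```r
library(tsann)

pf  <- planted_factor("RISK.A", effect_logit = 5, prevalence = 0.5)
cfg <- sim_config(800, target_case_fraction = 0.5, baseline_logit = -2.5,
                  planted_factors = list(pf), seed = 7)
sim <- generate_cohort(cfg)

cohort <- build_cohort(sim$patients, sim$events, read_med_classes())
vocab  <- build_vocabulary(cohort$cohort)
encs   <- encode_cohort(cohort$cohort, vocab)
split  <- make_splits(vapply(encs, `[[`, integer(1), "label"), seed = 7)

model <- init_model(vocab$size, "TSANN_I", D_c = 16, m = 8, H = 16, seed = 7)
fit   <- train_model(model, encs[split$train], encs[split$test],
                     epochs = 4, learning_rate = 0.005, seed = 7,
                     verbose = TRUE)
#> epoch 1 loss 0.7144 val AUC 0.6168
#> epoch 2 loss 0.6831 val AUC 0.6710
#> epoch 3 loss 0.4147 val AUC 0.8908
#> epoch 4 loss 0.2118 val AUC 0.9115

preds <- predict_cohort(fit$model, encs[split$test])
auc_score(preds$score, preds$label)
#> [1] 0.9115...

contribs <- cohort_contributions(fit$model, encs[split$test])
head(cohort_level_factors(contribs), 5)
#>         code month_bucket    score support
#> 1  DX:RISK.A            0 3.512166      21
#> 2  DX:RISK.A            2 2.382590      15
#> 3 RACE_WHITE            0 2.116252      37
#> 4  DX:RISK.A            1 1.463315       9
#> 5     AGE_30            0 1.431467      26
```

The planted code dominates the factor ranking (month buckets 0–2 because
its occurrences are spread across the window), the held-out AUC ≈ 0.91
approaches the ceiling implied by the +5 log-odds effect, and
`patient_contributions()` / `render_heatmap()` produce the per-patient
view. A command-line wrapper with `simulate` / `cohort` / `encode` /
`train` / `gridsearch` / `interpret` subcommands lives at
`inst/cli/tsann.R`.

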