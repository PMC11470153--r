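# msnote

Hierarchical multi-note classification of clinical social work notes, with
topic-level attribution to social determinants of health (SDOH).

## The problem

Clinical social work notes document the non-clinical circumstances of a
patient's life — mental health, family support, housing, abuse history,
insurance and income — rather than diagnoses or treatment plans. Whether
such documentation is *predictive* of the therapy a patient ultimately
receives is a health-disparities question: if a classifier can read only
social work notes and predict whether a breast-cancer patient ever received
targeted therapy, the notes carry signal about treatment allocation that
has nothing to do with tumor biology.

`msnote` implements that analysis end to end for researchers in clinical
NLP and health-disparities informatics:

1. **Labeling** — a patient is `TT-Yes` if their medication history
   contains at least one targeted-therapy drug (case-insensitive name match
   against a drug lexicon), `TT-No` otherwise.
2. **Masking** — every known drug name in the note text is replaced by the
   literal token `drug` before any modeling, so the label cannot leak
   through drug mentions ("Tamoxifen was administered to the patient" →
   "drug was administered to the patient").
3. **Single-note model** — each patient's *primary* note (most recent day,
   longest that day) is classified by a trainable encoder: a note is the
   mean of its token embeddings, h = (1/L) Σᵢ E[tᵢ], fed to a logistic
   head, trained end to end with cross-entropy and early stopping on
   validation loss. The encoder is pluggable; the default is desk-scale.
4. **Hierarchical MS-n model** — most patients have many notes (median 11).
   MS-n integrates up to n of them in two phases: phase 1 broadcasts the
   patient label to every note and fine-tunes the note model on all
   training notes; phase 2 freezes the encoder, concatenates each
   patient's n most recent note representations z = [h₁; …; hₙ]
   (zero-padded), and trains a one-hidden-layer MLP head on z.
5. **Evaluation** — AUROC (Mann–Whitney, ties ½) and macro-averaged
   F1/precision/recall, with prior/stratified/uniform dummy baselines and
   median-over-5-runs reporting.
6. **Topic ablation** — for each SDOH topic, delete its keywords from the
   *test set only*, re-run inference, and report the drop in macro F1
   (ΔF1), plus ΔF1 normalized by the topic's note-level frequency.

Because real social work notes cannot be redistributed, the package ships a
synthetic-corpus generator (`generate_corpus()`) that reproduces the
corpus's statistical shape — 70/30 label prevalence, heavy-tailed
notes-per-patient counts (mode ≈ 1–2, median ≈ 11, mean ≈ 22), topic
frequencies spanning 10%–96% of notes, drug mentions in < 10% of notes —
with *known, planted* class-dependent topic effects, so every pipeline
stage is verifiable against ground truth.

## Worked example

```r
library(msnote)
lexicon <- sdoh_topics()
drugs   <- drug_lexicon()

spec <- synthetic_spec(
  n_patients    = 600,
  topic_effects = default_topic_effects(lexicon, effect = 0.3),
  seed          = 11)
corpus <- generate_corpus(spec, lexicon, drugs)
cohort <- build_cohort(corpus$notes, corpus$medications, drugs, seed = 11)

ms5 <- ms_classifier(cohort$notes[, c("patient_id","note_id","timestamp","text")],
                     cohort$patients, config = ms_config(n = 5),
                     train_cfg = train_config(seed = 11))

test_patients <- cohort$patients[cohort$patients$split == "test", ]
test_notes    <- cohort$notes[cohort$notes$split == "test",
                              c("patient_id","note_id","timestamp","text")]
scores <- predict(ms5, test_notes)[test_patients$patient_id]
print(metric_report(test_patients$label, scores))

imp <- ablation_importance(ms5, test_notes,
                           setNames(test_patients$label, test_patients$patient_id),
                           lexicon)
print(imp)
```

Output (abridged):

```
Synthetic note corpus: 600 patients, 12602 notes
  TT-Yes prevalence: 0.717 (spec 0.70)
  notes per patient: median 12, mean 21.0
AUROC 0.997 | macro F1 0.963 | macro precision 0.952 | macro recall 0.976 (n = 60)
Topic-ablation importance (baseline macro F1 0.963)
                                     topic delta_f1 frequency normalized
             Clinician/Hospital/Medication   0.2962    0.8519     0.3477
 Living condition/Lifestyle/Social support   0.2478    0.8559     0.2895
                                    Family   0.1682    0.7842     0.2145
                             Mental health   0.0869    0.7359     0.1181
 ...
```

Every topic here carries the same planted class effect (0.3), so the raw
ΔF1 column tracks how *often* a topic is mentioned, while the
frequency-normalized column is far more even — exactly the confound the
normalization corrects. The metric line says the MS-5 model separates
TT-Yes from TT-No patients almost perfectly on this corpus; on a corpus
with *no* planted effect the same pipeline scores at chance (see the
null-calibration experiment).

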