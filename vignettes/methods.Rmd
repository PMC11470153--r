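---
title: "Methods: hierarchical note classification and topic ablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical note classification and topic ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`msnote` predicts a binary patient-level outcome — ever received targeted
therapy (`TT-Yes`) or not (`TT-No`) — from the free text of clinical social
work notes, and attributes the prediction to social-determinants-of-health
(SDOH) topics by keyword ablation. This vignette is the package's own
account of the modeling choices: what is assumed, what is tunable, what the
synthetic corpora do and do not establish, and where genuinely open design
questions were settled.

# Cohort construction

**Labeling.** A patient is `TT-Yes` when their medication list intersects a
targeted-therapy drug lexicon under case-insensitive exact-name matching.
An empty medication list is a valid `TT-No`. The lexicon is caller-supplied
(`drug_lexicon()`, `read_drug_lexicon()`) and is treated as exhaustive:
whether brand and generic names are covered jointly is a property of the
supplied list, not of the code.

**Masking.** Because a drug mention is the label in disguise, every
*maskable* name (a superset of the targeted set) is replaced by the literal
token `drug` before any modeling. Matching is case-insensitive, whole-word,
longest-phrase-first, so `drugstore` is never masked and a multi-word name
wins over its components. Adjacent punctuation is preserved. Masking is
idempotent, and the package's leakage contract is scanned in tests: after
`build_cohort()` no modeling input contains any maskable name.

**Primary note.** "The latest and the longest" note is ambiguous when the
latest note is not the longest. Decision: restrict to the patient's most
recent calendar day with notes, then take the longest note that day by
whitespace token count, breaking remaining ties toward the larger
`note_id`. This honors both words and is deterministic. Token counting is
whitespace-based so that note length is encoder-independent.

**Splitting.** Patients are split 8:1:1 into train/validation/test with
sizes `floor(0.8N)`, `floor(0.1N)` and the remainder — the held-out test
set absorbs rounding and is never smaller than nominal. The split is at
patient level; notes inherit their patient's split, so no note of a test
patient is ever seen in training, in either phase of the hierarchical
model. The five repeated "runs" of the reporting protocol re-seed training
only; the split is fixed once.

# The note model

A note is tokenized (lower-cased, punctuation stripped, whitespace split)
and truncated to the leading `max_tokens` tokens (default 512, the
standard encoder input limit; truncation keeps the head of the note).
Empty text becomes a single unknown token rather than an error.

The default encoder is deliberately desk-scale: token embeddings
`E` (vocabulary × d, d = 32) mean-pooled over the note,

$$h = \frac{1}{L}\sum_{i=1}^{L} E[t_i],$$

with a logistic head on `h`. Embeddings and head are trained jointly
(the "fine-tuning" of this encoder) by full-batch gradient descent with
classical momentum under the cross-entropy loss. Any larger pre-trained
encoder can stand behind the same contract — a deterministic map from a
token sequence to a fixed-length vector — but the pipeline's logic is
encoder-agnostic and all validation here uses the default.

**Why momentum SGD and not an adaptive optimizer.** Mean pooling makes
every feature small (a token contributes 1/L ≈ 1/80 of a unit), so raw
gradients are small and *informative in magnitude*: the consistent
keyword-class correlation produces persistently larger gradient components
than background-token noise. Plain momentum SGD amplifies exactly those.
An adaptive per-coordinate method normalizes that magnitude information
away — in our sweeps it behaved like sign-SGD, memorizing background
tokens and overfitting within a handful of epochs. The default learning
rate (3) is far above mini-batch conventions because it acts on full-batch
gradients of 1/L-scaled features.

**Early stopping.** Training stops once validation loss has failed to
improve for more than `patience` consecutive epochs, and the
best-validation parameters are restored; validation loss is the stopping
metric (the natural choice when no other is named), the improvement
threshold is 1e-9, and `patience = 0` stops at the first non-improvement.
The default patience is generous (60 epochs, with `max_epochs = 400`)
because the momentum dynamics on weak-signal corpora pass through long
stretches — up to ~90 epochs in our traces — where validation loss
oscillates around a slowly improving trend without setting a new best. A
conventional patience of 3–5 reliably stops inside such a stretch and
returns a chance-level model on corpora that are in fact learnable; we
verified this by training to a fixed horizon and watching validation loss
descend monotonically long after a short patience would have fired.
Head-weight initialization (sd 0.5) matters for the same reason: with a
near-zero head, no gradient reaches the embeddings and the bilinear
saddle at the origin is slow to escape.

**Numerical safety.** Probabilities are clamped at 1e-12 inside the
cross-entropy, so a confident wrong prediction yields a large finite loss;
a non-finite training loss aborts with a diagnostic rather than
propagating NaNs. A single-class training split is an error, not a
warning.

# The hierarchical MS-n model

Phase 1 broadcasts the patient label to each of the patient's notes and
fine-tunes the note model on all training-patient notes (validation-patient
notes drive early stopping). Phase 2 extracts the pooled representation of
every note under the phase-1 parameters, freezes them, concatenates up to
`n` representations per patient, and trains a one-hidden-layer MLP head
(width 64, tanh) on the patient vectors with the same early-stopped
trainer. Only head parameters change in phase 2 — tests assert the
encoder parameters are bit-identical before and after.

Three choices the two-phase design leaves open were settled as follows:

* **Which notes when a patient has more than n:** the n most recent,
  matching the recency convention of the single-note model.
* **Order within the concatenation:** chronological, oldest of the
  selected notes first — a stable canonical order, so construction is
  invariant to input permutation (ties in timestamps fall back to input
  order).
* **Padding when a patient has fewer than n:** zero blocks plus an
  explicit mask. The default head consumes the zeros directly (a plain
  MLP); the mask is available for mask-aware heads.

With `n = 1` the pipeline reduces to a head retrained on single-note
representations of each patient's most recent note.

# Evaluation

AUROC is computed by midranks (the Mann–Whitney formulation: ties count
one half), which tests verify against exhaustive concordant-pair counting
and against an independent ROC implementation. Macro metrics average the
two per-class scores with equal weight; a class never predicted
contributes precision 0, which is what makes the constant-predictor
closed forms exact: on a test set with positive fraction q, the
most-frequent-class baseline has macro F1 = q/(1+q), macro precision =
q/2, macro recall = 1/2, and AUROC = 1/2 by the tie convention. At
q = 0.7 these are 0.412, 0.350, 0.5, 0.5. Hard predictions use threshold
0.5. Per-metric medians over runs use the midpoint convention.

# Topic ablation

For each topic independently, every occurrence of its keywords is
*deleted* from the test texts (placeholder substitution was considered and
rejected as a default: deletion is the closest literal reading of removing
a word set), the fitted model re-scores the ablated test set without any
retraining, and the importance is the drop in macro F1 from the unablated
baseline. Each topic's ablation starts from the pristine test set, so
topic A's result never depends on topic B. Training and validation data
are untouched throughout.

Raw ΔF1 confounds effect with prevalence — a ubiquitous topic can shed
more F1 than a rare, highly informative one — so the package also reports
ΔF1 divided by the topic's note-level frequency (simple division; no
regression adjustment). A topic that never occurs in the test set has
undefined normalized importance: flagged `NA`, with ΔF1 still reported.
ΔF1 may legitimately be negative (run noise). Ablation defaults to the
MS-5 model in the experiment harness but accepts any fitted classifier,
and F1 means macro F1 throughout, consistent with the evaluation module.

# The synthetic corpus generator

`generate_corpus()` is the package's ground-truth instrument, not a
simulation of clinical language. Each patient draws a label
(Bernoulli, prevalence 0.70), a note count, and notes consisting of
background filler tokens plus, independently per note and topic, one
randomly chosen keyword of the topic included with probability `p_pos` or
`p_neg` according to the patient's label. Multi-word keywords are inserted
as contiguous runs at a uniformly random position. A fraction of notes
(default 0.08, matching the sub-10% observation) carries a templated drug
sentence naming one of the patient's own medications, so masking is
exercised in realistic context. Medication tables are label-consistent:
every `TT-Yes` patient has a targeted drug, no `TT-No` patient does.
Timestamps are strictly increasing per patient, so "latest" is always
well defined. Identical spec and seed reproduce the corpus byte for byte.

**Note counts.** The per-patient note count is a shifted negative binomial
`1 + NB(size, mu)` with defaults `size = 0.55, mu = 21`. Within this
family, a mean of 22 and a median of 11 cannot coexist with a mode of
exactly 2: matching mean and median forces `size ≈ 0.55`, whose mode is 1.
We match median and mean — the two summaries that drive how much signal
MS-n can aggregate — and accept a sample mode of 1–2.

**Topic frequencies.** Default marginal note-level frequencies span 0.10
(risk of death) to 0.96 (living condition/social support), the observed
range in real social work notes. Given a marginal frequency f and a
planted effect δ = p_pos − p_neg, the generator uses
p_pos = f + (1 − q)δ and p_neg = f − qδ (q the prevalence), which keeps
the marginal at f exactly — so frequency calibration and effect strength
are independent dials.

**Scale defaults.** Background vocabulary 500 types and mean note length
80 tokens (Poisson, floored at 10) for full-size corpora. Small test
corpora use proportionally smaller vocabularies (Heaps' law: a 200-note
corpus does not expose 500 word types); this matters because at 200
training notes and 500 background types even a cross-validated ridge
oracle on the same features cannot exceed AUROC ≈ 0.85 — the regime is
information-poor for any dense model, which is a property of the corpus,
not the trainer.

**What the generator does not emulate** — and hence what passing tests do
not establish about real notes: grammar and discourse structure, negation
("denies abuse"), misspellings and abbreviations, topic correlation
within and across notes, temporal drift in documentation style, and any
relationship between note *content* and note *count*. Lexical-presence
signal is the only planted structure, because every pipeline stage under
test operates on lexical presence.

# Validation experiments

Four pre-registered experiment functions fix the study conditions so that
tests and the acceptance script run identical designs; sizes were chosen
to give comfortable statistical margins at single-core, minutes-scale
runtimes.

* `experiment_corpus_calibration()` — 2,000 patients; checks prevalence
  and per-topic frequencies within three binomial standard deviations and
  the note-count summaries (mode 1–3, median 9–13, mean 18–26).
* `experiment_null_calibration()` — 600 patients, every topic at
  p_pos = p_neg; the note classifier's held-out AUROC over five runs must
  sit in [0.4, 0.6]. Evaluation is at note level (≈ 1,200 test notes), so
  the chance band is comfortably wider than the estimator's noise.
* `experiment_ms_benefit()` — 800 patients, every topic at effect 0.15:
  individually weak per-note signal present in every note. Single-note
  and MS-5 arms share configs and seeds; the claim verified is the
  qualitative one — median MS-5 macro F1 at least matches the single-note
  model — not any particular real-data value.
* `experiment_importance_recovery()` — 2,000 patients, six topics at
  equal marginal frequency 0.5 with strictly ordered effects 0.05–0.45;
  MS-5 plus ablation must recover the ordering (median Spearman ≥ 0.8,
  top topic correct in ≥ 4 of 5 runs). Equal frequencies isolate effect
  recovery from the frequency confound; the frequency dial is exercised
  separately by the calibration experiment.

# Limitations

The default encoder is a linear bag-of-embeddings: it cannot represent
word order, negation, or interactions, and conclusions about *which*
encoder family performs best on real notes are out of scope. Masking is
lexicon-bounded: names absent from the maskable list leak by definition.
The ablation attributes importance only through the supplied keyword
lists — a topic expressed in words outside its list is invisible to both
the planted-signal generator and the ablation. Real-data performance
numbers are not reproduced here; they require private clinical text and
GPU-scale encoders, and the synthetic experiments validate pipeline
correctness, not clinical effect sizes.
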