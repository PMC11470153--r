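# Pre-registered validation experiments on synthetic corpora. Each function
# fixes the study conditions (corpus size, planted effects, number of runs)
# and takes only a seed, so tests and scripts exercise identical designs.
# Problem sizes are chosen to keep each experiment in the minutes range on a
# single core while leaving comfortable statistical margins; the rationale is
# laid out in the methods vignette.

#' Null-calibration experiment: chance-level AUROC without planted signal
#'
#' Generates a corpus in which every topic has p_pos = p_neg (no
#' class-dependent signal), trains the single-note classifier on the
#' broadcast note-level instances, and evaluates AUROC on the held-out test
#' notes, repeating over `n_runs` training seeds. With no signal the median
#' AUROC must sit near 0.5.
#'
#' @param n_patients corpus size (default 600).
#' @param n_runs repeated training runs (default 5).
#' @param seed base seed; run r trains with seed `seed * 100 + r`.
#' @return list with `auroc_runs`, `median_auroc`, `n_test_notes`.
#' @export
experiment_null_calibration <- function(n_patients = 600, n_runs = 5,
                                        seed = 1L) {
  lex <- sdoh_topics()
  spec <- synthetic_spec(
    n_patients = n_patients,
    topic_effects = default_topic_effects(lex, effect = 0),
    seed = seed)
  corpus <- generate_corpus(spec, lex, drug_lexicon())
  ch <- build_cohort(corpus$notes, corpus$medications, drug_lexicon(),
                     seed = seed)
  tr <- ch$notes[ch$notes$split == "train", c("text", "label")]
  va <- ch$notes[ch$notes$split == "validation", c("text", "label")]
  tst <- ch$notes[ch$notes$split == "test", c("text", "label")]
  aucs <- vapply(seq_len(n_runs), function(r) {
    fit <- note_classifier(tr, va,
                           config = train_config(seed = seed * 100L + r))
    auroc(tst$label, predict(fit, tst$text))
  }, 0)
  list(auroc_runs = aucs, median_auroc = stats::median(aucs),
       n_test_notes = nrow(tst))
}

# six equal-frequency SDOH topics carrying strictly ordered planted effects
importance_design <- function() {
  lex <- sdoh_topics()
  topics <- c("Mental health", "Family", "Group session", "Risk of death",
              "Abuse history", "Insurance/Income")
  lex6 <- topic_lexicon(unclass(lex)[topics])
  effects <- c(0.05, 0.13, 0.21, 0.29, 0.37, 0.45)
  names(effects) <- topics
  list(lexicon = lex6,
       effects = effects,
       topic_effects = default_topic_effects(
         lex6, frequencies = stats::setNames(rep(0.5, 6), topics),
         effect = effects))
}

#' Importance-recovery experiment: ablation ranks the planted effects
#'
#' Generates a 2,000-patient corpus with six SDOH topics at equal marginal
#' frequency (0.5) but strictly ordered class effects |p_pos - p_neg| =
#' 0.05 ... 0.45, fits the MS-5 model, runs the topic-ablation sweep on the
#' test patients, and scores recovery: Spearman correlation between the
#' delta-F1 importances and the planted effects, and whether the top-ranked
#' topic is the largest planted effect. Repeated over `n_runs` seeds.
#'
#' @param n_patients corpus size (default 2000).
#' @param n_runs repeated runs (default 5).
#' @param seed base seed.
#' @return list with per-run `spearman`, `top_match`, `baseline_f1`, the
#'   medians, and the count of top-1 agreements.
#' @export
experiment_importance_recovery <- function(n_patients = 2000, n_runs = 5,
                                           seed = 1L) {
  des <- importance_design()
  spec <- synthetic_spec(n_patients = n_patients,
                         topic_effects = des$topic_effects, seed = seed)
  corpus <- generate_corpus(spec, des$lexicon, drug_lexicon())
  ch <- build_cohort(corpus$notes, corpus$medications, drug_lexicon(),
                     seed = seed)
  cols <- c("patient_id", "note_id", "timestamp", "text")
  tst <- ch$patients[ch$patients$split == "test", ]
  tn <- ch$notes[ch$notes$split == "test", cols]
  lab <- stats::setNames(tst$label, tst$patient_id)
  runs <- lapply(seq_len(n_runs), function(r) {
    ms <- ms_classifier(ch$notes[, cols], ch$patients,
                        config = ms_config(n = 5),
                        train_cfg = train_config(seed = seed * 100L + r))
    imp <- ablation_importance(ms, tn, lab, des$lexicon)
    rec <- importance_recovery(imp, corpus$truth)
    list(spearman = rec$spearman_delta,
         spearman_normalized = rec$spearman_normalized,
         top_match = rec$top_match,
         baseline_f1 = attr(imp, "baseline_f1"))
  })
  list(spearman = vapply(runs, `[[`, 0, "spearman"),
       spearman_normalized = vapply(runs, `[[`, 0, "spearman_normalized"),
       top_match = vapply(runs, `[[`, TRUE, "top_match"),
       baseline_f1 = vapply(runs, `[[`, 0, "baseline_f1"),
       median_spearman = stats::median(vapply(runs, `[[`, 0, "spearman")),
       n_top_match = sum(vapply(runs, `[[`, TRUE, "top_match")))
}

#' MS-n benefit experiment: aggregation beats the single-note model
#'
#' Generates a corpus whose per-note signal is weak (every default topic at
#' effect 0.15) but present in every note, then compares the single-note
#' classifier (trained on the primary latest-longest note per patient)
#' against MS-5 at matched training seeds, reporting per-run patient-level
#' metrics and their medians.
#'
#' @param n_patients corpus size (default 800).
#' @param n_runs repeated runs (default 5).
#' @param seed base seed.
#' @details The single-note and MS-5 arms train with the same default
#'   configuration at matched seeds, so the comparison isolates the effect
#'   of note aggregation.
#' @return list with per-run `single` and `ms5` metric reports plus
#'   `median_single` and `median_ms5` (run summaries).
#' @export
experiment_ms_benefit <- function(n_patients = 800, n_runs = 5, seed = 1L) {
  lex <- sdoh_topics()
  spec <- synthetic_spec(
    n_patients = n_patients,
    topic_effects = default_topic_effects(lex, effect = 0.15),
    seed = seed)
  corpus <- generate_corpus(spec, lex, drug_lexicon())
  ch <- build_cohort(corpus$notes, corpus$medications, drug_lexicon(),
                     seed = seed)
  cols <- c("patient_id", "note_id", "timestamp", "text")
  tst <- ch$patients[ch$patients$split == "test", ]
  tn <- ch$notes[ch$notes$split == "test", cols]
  single <- list(); ms5 <- list()
  for (r in seq_len(n_runs)) {
    cfg <- train_config(seed = seed * 100L + r)
    f1 <- note_classifier(ch$primary[ch$primary$split == "train", ],
                          ch$primary[ch$primary$split == "validation", ],
                          config = cfg)
    s1 <- predict(f1, ch$primary$text[ch$primary$split == "test"])
    single[[r]] <- metric_report(tst$label, s1, run_seed = cfg$seed)
    ms <- ms_classifier(ch$notes[, cols], ch$patients,
                        config = ms_config(n = 5), train_cfg = cfg)
    s5 <- unname(predict(ms, tn)[tst$patient_id])
    ms5[[r]] <- metric_report(tst$label, s5, run_seed = cfg$seed)
  }
  list(single = single, ms5 = ms5,
       median_single = median_over_runs(single),
       median_ms5 = median_over_runs(ms5))
}

#' Corpus-calibration experiment: generated statistics match their targets
#'
#' Generates the default-size corpus and measures label prevalence, per-topic
#' note-level keyword frequencies, the note-count distribution summaries and
#' the drug-mention rate, alongside their targets.
#'
#' @param seed corpus seed.
#' @param n_patients corpus size (default 2000).
#' @return list of observed statistics and targets.
#' @export
experiment_corpus_calibration <- function(seed = 1L, n_patients = 2000) {
  lex <- sdoh_topics()
  spec <- synthetic_spec(n_patients = n_patients, seed = seed)
  corpus <- generate_corpus(spec, lex, drug_lexicon())
  counts <- as.integer(table(corpus$notes$patient_id))
  freqs <- vapply(names(lex), function(t)
    topic_frequency(corpus$notes$text, lex[[t]]), 0)
  drugs <- drug_lexicon()
  drug_rate <- 1 - nrow(drug_free_subset(corpus$notes, drugs)) /
    nrow(corpus$notes)
  list(prevalence = mean(corpus$truth$patient_labels == "TT-Yes"),
       prevalence_target = spec$prevalence,
       n_patients = n_patients,
       notes_total = nrow(corpus$notes),
       count_mode = as.integer(names(which.max(table(counts)))),
       count_median = stats::median(counts),
       count_mean = mean(counts),
       topic_frequencies = freqs,
       topic_frequency_targets = default_topic_frequencies()[names(lex)],
       drug_rate = drug_rate,
       drug_rate_target = spec$drug_mention_rate)
}
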