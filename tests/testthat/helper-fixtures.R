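# shared fixtures and independent oracles, built in code

fixture_drugs <- function() drug_lexicon()

# two-topic lexicon with distinctive single-token keywords
fixture_lex2 <- function() {
  topic_lexicon(list(Alpha = "kwalpha", Beta = "kwbeta"))
}

# small perfectly separable corpus: Alpha carries all signal
separable_corpus <- function(n_patients = 250, seed = 5) {
  spec <- synthetic_spec(
    n_patients = n_patients,
    topic_effects = list(Alpha = c(1, 0), Beta = c(0.5, 0.5)),
    drug_mention_rate = 0,
    background_vocab_size = 100,
    mean_note_length = 40,
    seed = seed)
  generate_corpus(spec, fixture_lex2(), fixture_drugs())
}

# brute-force AUROC oracle: explicit concordant-pair count, ties half
auroc_pairs <- function(labels, scores) {
  y <- as_binary_label(labels)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# hand-rolled notes table for cohort tests
toy_notes <- function() {
  data.frame(
    patient_id = c("A", "A", "A", "B"),
    note_id = c("n1", "n2", "n3", "n4"),
    timestamp = c("2020-01-01T09:00:00", "2020-01-05T09:00:00",
                  "2020-01-09T09:00:00", "2020-02-01T09:00:00"),
    text = c(paste(rep("tok", 100), collapse = " "),
             paste(rep("tok", 400), collapse = " "),
             paste(rep("tok", 50), collapse = " "),
             "short note"),
    stringsAsFactors = FALSE)
}
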