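test_that("note-count distribution matches the heavy-tailed cohort shape", {
  spec <- synthetic_spec(seed = 1)
  x <- sample_note_counts(spec, 2000)
  expect_true(all(x >= 1))
  mode_x <- as.integer(names(which.max(table(x))))
  expect_gte(mode_x, 1)
  expect_lte(mode_x, 3)
  expect_gte(median(x), 9)
  expect_lte(median(x), 13)
  expect_gte(mean(x), 18)
  expect_lte(mean(x), 26)
})

test_that("note-count sampling is deterministic and handles the point mass", {
  spec <- synthetic_spec(seed = 9)
  expect_identical(sample_note_counts(spec, 500), sample_note_counts(spec, 500))
  deg <- synthetic_spec(note_count_params = list(size = 1, mu = 0), seed = 2)
  expect_identical(sample_note_counts(deg, 5), rep(1L, 5))
  expect_error(synthetic_spec(note_count_params = list(size = -1, mu = 5)),
               "note-count")
})

test_that("spec validation rejects out-of-range probabilities", {
  expect_error(synthetic_spec(prevalence = 0), "prevalence")
  expect_error(synthetic_spec(prevalence = 1), "prevalence")
  expect_error(synthetic_spec(drug_mention_rate = 1), "drug_mention_rate")
  expect_error(synthetic_spec(topic_effects = list(A = c(1.2, 0))), "probabilities")
})

test_that("label prevalence is binomially calibrated", {
  spec <- synthetic_spec(n_patients = 2496, prevalence = 0.7, seed = 7,
                         background_vocab_size = 50, mean_note_length = 10,
                         note_count_params = list(size = 1, mu = 1))
  corpus <- generate_corpus(spec, fixture_lex2(), fixture_drugs())
  npos <- sum(corpus$truth$patient_labels == "TT-Yes")
  sd3 <- 3 * sqrt(2496 * 0.7 * 0.3)
  expect_lt(abs(npos - 2496 * 0.7), sd3)
})

test_that("generation is deterministic given spec and seed", {
  spec <- synthetic_spec(n_patients = 30, seed = 11, mean_note_length = 15)
  a <- generate_corpus(spec, fixture_lex2(), fixture_drugs())
  b <- generate_corpus(spec, fixture_lex2(), fixture_drugs())
  expect_identical(a$notes, b$notes)
  expect_identical(a$medications, b$medications)
  expect_identical(a$truth, b$truth)
})

test_that("topic keyword frequencies are calibrated to the planted marginals", {
  lex <- sdoh_topics()
  spec <- synthetic_spec(n_patients = 100, seed = 3)  # ~2000 notes
  corpus <- generate_corpus(spec, lex, fixture_drugs())
  n <- nrow(corpus$notes)
  expect_gt(n, 1500)
  freqs <- default_topic_frequencies()
  for (t in c("Living condition/Lifestyle/Social support", "Risk of death",
              "Insurance/Income")) {
    f <- freqs[[t]]
    obs <- topic_frequency(corpus$notes$text, lex[[t]])
    expect_lt(abs(obs - f), 3 * sqrt(f * (1 - f) / n) + 1e-9)
  }
})

test_that("a null topic shows no class-dependent frequency difference", {
  spec <- synthetic_spec(n_patients = 100, seed = 13,
                         topic_effects = list(Alpha = c(0.5, 0.5),
                                              Beta = c(0.5, 0.5)))
  corpus <- generate_corpus(spec, fixture_lex2(), fixture_drugs())
  lab <- corpus$truth$patient_labels[corpus$notes$patient_id]
  hit <- grepl("kwalpha", corpus$notes$text, fixed = TRUE)
  n1 <- sum(lab == "TT-Yes"); n0 <- sum(lab == "TT-No")
  p1 <- mean(hit[lab == "TT-Yes"]); p0 <- mean(hit[lab == "TT-No"])
  pp <- mean(hit)
  z <- (p1 - p0) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n0))
  expect_lt(abs(z), qnorm(0.995))
})

test_that("drug mentions obey the configured rate and vanish at rate zero", {
  drugs <- fixture_drugs()
  pat <- paste0("(?i)", paste(drugs$maskable, collapse = "|"))
  spec0 <- synthetic_spec(n_patients = 50, drug_mention_rate = 0, seed = 4)
  c0 <- generate_corpus(spec0, fixture_lex2(), drugs)
  expect_identical(sum(grepl(pat, c0$notes$text, perl = TRUE)), 0L)

  spec8 <- synthetic_spec(n_patients = 100, drug_mention_rate = 0.08, seed = 4)
  c8 <- generate_corpus(spec8, fixture_lex2(), drugs)
  rate <- mean(grepl(pat, c8$notes$text, perl = TRUE))
  n <- nrow(c8$notes)
  expect_lt(abs(rate - 0.08), 3 * sqrt(0.08 * 0.92 / n))
  expect_lt(rate, 0.10)
})

test_that("medication tables are consistent with labels", {
  drugs <- fixture_drugs()
  corpus <- generate_corpus(synthetic_spec(n_patients = 80, seed = 21,
                                           mean_note_length = 15),
                            fixture_lex2(), drugs)
  meds_by <- split(corpus$medications$drug_name, corpus$medications$patient_id)
  for (p in names(corpus$truth$patient_labels)) {
    has_tt <- any(tolower(meds_by[[p]]) %in% drugs$targeted)
    expect_identical(has_tt, corpus$truth$patient_labels[[p]] == "TT-Yes")
  }
})

test_that("oracle keyword rule is perfect on the separable corpus", {
  corpus <- separable_corpus(120, seed = 8)
  lab <- corpus$truth$patient_labels[corpus$notes$patient_id]
  pred <- as.integer(grepl("kwalpha", corpus$notes$text, fixed = TRUE))
  mm <- macro_metrics(lab, pred)
  expect_equal(unname(mm["macro_f1"]), 1.0)
})

test_that("generator rejects inconsistent lexicon/effect configurations", {
  spec <- synthetic_spec(n_patients = 5,
                         topic_effects = list(Alpha = c(0.5, 0.5)))
  expect_error(generate_corpus(spec, fixture_lex2(), fixture_drugs()),
               "missing topic")
  expect_error(topic_lexicon(list()), "non-empty")
})

test_that("timestamps are strictly increasing within each patient", {
  corpus <- generate_corpus(synthetic_spec(n_patients = 40, seed = 6,
                                           mean_note_length = 12),
                            fixture_lex2(), fixture_drugs())
  by_pat <- split(corpus$notes$timestamp, corpus$notes$patient_id)
  expect_true(all(vapply(by_pat, function(ts)
    all(diff(as.Date(substr(ts, 1, 10))) > 0), TRUE)))
})

test_that("corpus round-trips through the interchange formats", {
  corpus <- generate_corpus(synthetic_spec(n_patients = 8, seed = 15,
                                           mean_note_length = 12),
                            fixture_lex2(), fixture_drugs())
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  notes <- read_notes_jsonl(file.path(dir, "notes.jsonl"))
  expect_equal(notes, corpus$notes)
  meds <- read_medications(file.path(dir, "medications.csv"))
  expect_equal(meds, corpus$medications)
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  expect_equal(unlist(gt$patient_labels), corpus$truth$patient_labels)
})
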