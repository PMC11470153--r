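test_that("keyword deletion removes whole words, keeps order, idempotent", {
  expect_identical(remove_topic_words("patient reports abuse at home", "abuse"),
                   "patient reports at home")
  plain <- "routine visit with daughter"
  expect_identical(remove_topic_words(plain, "housing"), plain)
  once <- remove_topic_words("ABUSE then abuse.", "abuse")
  expect_identical(once, "then .")
  expect_identical(remove_topic_words(once, "abuse"), once)
  # phrases removed as contiguous runs; embedded matches untouched
  expect_identical(
    remove_topic_words("attended group session on coping", "group session"),
    "attended on coping")
  expect_identical(remove_topic_words("abuser stayed", "abuse"),
                   "abuser stayed")
})

test_that("topic frequency counts notes with any keyword", {
  texts <- c("insurance denied", "spoke with daughter", "INSURANCE ok",
             "nothing here")
  expect_equal(topic_frequency(texts, c("insurance", "income")), 0.5)
  expect_equal(topic_frequency(texts, "hospice"), 0)
  expect_equal(topic_frequency(texts, c("insurance", "daughter", "nothing")),
               1.0)
  expect_error(topic_frequency(character(0), "x"), "non-empty")
})

test_that("ablating the sole signal topic collapses F1 toward the prior", {
  corpus <- separable_corpus(250, seed = 12)
  ch <- build_cohort(corpus$notes, corpus$medications, fixture_drugs(),
                     seed = 4)
  fit <- note_classifier(ch$primary[ch$primary$split == "train", ],
                         ch$primary[ch$primary$split == "validation", ],
                         config = train_config(seed = 2))
  tst <- ch$primary[ch$primary$split == "test", ]
  imp <- ablation_importance(fit, tst$text, tst$label, fixture_lex2())
  expect_s3_class(imp, "importance_scores")
  expect_identical(imp$topic, c("Alpha", "Beta"))
  base <- attr(imp, "baseline_f1")
  expect_gte(base, 0.9)
  # signal topic: large drop; ablated input is uninformative, so the model
  # lands near a constant predictor whose macro F1 is bounded by q/(1+q)
  a <- imp[imp$topic == "Alpha", ]
  expect_gt(a$delta_f1, 0.3)
  q <- mean(tst$label == "TT-Yes")
  expect_lte(base - a$delta_f1, q / (1 + q) + 0.1)
  # null topic barely moves
  expect_lt(abs(imp$delta_f1[imp$topic == "Beta"]), 0.1)
  # bounded damage
  expect_lte(a$delta_f1, base)
})

test_that("each ablation starts from the pristine test set", {
  corpus <- separable_corpus(120, seed = 14)
  ch <- build_cohort(corpus$notes, corpus$medications, fixture_drugs(),
                     seed = 4)
  fit <- note_classifier(ch$primary[ch$primary$split == "train", ],
                         ch$primary[ch$primary$split == "validation", ],
                         config = train_config(max_epochs = 40, patience = 5,
                                               seed = 2))
  tst <- ch$primary[ch$primary$split == "test", ]
  snapshot <- tst$text
  lex <- fixture_lex2()
  imp_ab <- ablation_importance(fit, tst$text, tst$label, lex)
  expect_identical(tst$text, snapshot)  # inputs untouched
  # results per topic do not depend on which other topics are in the sweep
  imp_ba <- ablation_importance(fit, tst$text, tst$label,
                                topic_lexicon(rev(unclass(lex))))
  for (t in imp_ab$topic) {
    expect_equal(imp_ab[imp_ab$topic == t, -1],
                 imp_ba[imp_ba$topic == t, -1],
                 ignore_attr = TRUE)
  }
})

test_that("normalization divides by frequency and flags absent topics", {
  df <- data.frame(topic = "X", delta_f1 = 0.06, frequency = 0.96,
                   normalized = 0.06 / 0.96)
  expect_equal(df$normalized, 0.0625)
  corpus <- separable_corpus(100, seed = 15)
  ch <- build_cohort(corpus$notes, corpus$medications, fixture_drugs(),
                     seed = 4)
  fit <- note_classifier(ch$primary[ch$primary$split == "train", ],
                         ch$primary[ch$primary$split == "validation", ],
                         config = train_config(max_epochs = 30, patience = 5,
                                               seed = 2))
  tst <- ch$primary[ch$primary$split == "test", ]
  lex <- topic_lexicon(list(Alpha = "kwalpha", Ghost = "neverseenword"))
  imp <- ablation_importance(fit, tst$text, tst$label, lex)
  g <- imp[imp$topic == "Ghost", ]
  expect_equal(g$frequency, 0)
  expect_true(is.na(g$normalized))     # flagged: undefined normalization
  expect_false(is.na(g$delta_f1))      # delta still reported
  a <- imp[imp$topic == "Alpha", ]
  expect_equal(a$normalized, a$delta_f1 / a$frequency)
})

test_that("importance recovery computes rank agreement against truth", {
  scores <- data.frame(topic = c("A", "B", "C", "D"),
                       delta_f1 = c(0.05, 0.10, 0.20, 0.40),
                       frequency = rep(0.5, 4),
                       normalized = c(0.10, 0.20, 0.40, 0.80))
  class(scores) <- c("importance_scores", "data.frame")
  attr(scores, "baseline_f1") <- 0.9
  truth <- structure(list(
    patient_labels = c(p1 = "TT-Yes"),
    topic_effect_sizes = c(A = 0.1, B = 0.2, C = 0.3, D = 0.4)),
    class = "ground_truth")
  rec <- importance_recovery(scores, truth)
  expect_equal(rec$spearman_delta, 1.0)
  expect_equal(rec$spearman_normalized, 1.0)
  expect_identical(rec$top_topic, "D")
  expect_true(rec$top_match)
  truth2 <- truth
  truth2$topic_effect_sizes <- truth2$topic_effect_sizes[c("A", "B")]
  expect_error(importance_recovery(scores, truth2), "at least 3")
})
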