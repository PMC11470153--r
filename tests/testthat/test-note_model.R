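test_that("tokenization truncates to the input-length limit", {
  long <- paste(sprintf("tok%d", 1:600), collapse = " ")
  t512 <- tokenize_truncate(long, 512)[[1]]
  expect_length(t512, 512)
  expect_identical(t512[1], "tok1")
  short <- tokenize_truncate("Just ten tokens here and nothing else at all ok",
                             512)[[1]]
  expect_length(short, 10)
  expect_length(tokenize_truncate(long, 1)[[1]], 1)
  expect_identical(tokenize_truncate("", 512)[[1]], "<unk>")
  expect_identical(tokenize_truncate("He said: STOP!", 512)[[1]],
                   c("he", "said", "stop"))
})

test_that("cross-entropy matches closed-form values and clamps zeros", {
  expect_equal(cross_entropy(c(0, 1), 2), 0)
  expect_equal(cross_entropy(c(0.5, 0.5), 1), log(2), tolerance = 1e-4)
  expect_equal(cross_entropy(c(0.1, 0.9), 1), 2.3026, tolerance = 1e-4)
  expect_equal(cross_entropy(c(yes = 0.25, no = 0.75), "no"), -log(0.75))
  expect_equal(cross_entropy(c(0, 1), 1), -log(1e-12))
  expect_error(cross_entropy(c(0.5, 0.4), 1), "sum to 1")
})

test_that("training recovers the planted keyword on a separable corpus", {
  # 200 train / 50 val note instances, patient-level split respected
  corpus <- separable_corpus(100, seed = 5)
  ch <- build_cohort(corpus$notes, corpus$medications, fixture_drugs(),
                     seed = 2)
  inst <- ch$notes
  tr <- inst[inst$split == "train", c("text", "label")]
  va <- inst[inst$split == "validation", c("text", "label")]
  set.seed(3)
  tr <- tr[sample(nrow(tr), 200), ]
  va <- va[sample(nrow(va), min(50, nrow(va))), ]
  fit <- note_classifier(tr, va, config = train_config(seed = 1))
  tst <- inst[inst$split == "test", ]
  scores <- predict(fit, tst$text)
  mm <- macro_metrics(tst$label, as.integer(scores >= 0.5))
  expect_gte(unname(mm["macro_f1"]), 0.9)
  # oracle directions: keyword note scores high, background note scores low
  expect_gt(mean(scores[grepl("kwalpha", tst$text)]), 0.5)
  expect_lt(mean(scores[!grepl("kwalpha", tst$text)]), 0.5)
})

test_that("prediction and representations are deterministic and shaped", {
  corpus <- separable_corpus(80, seed = 6)
  ch <- build_cohort(corpus$notes, corpus$medications, fixture_drugs(),
                     seed = 2)
  cfg <- train_config(max_epochs = 30, patience = 5, seed = 3)
  fit <- note_classifier(ch$primary[ch$primary$split == "train", ],
                         ch$primary[ch$primary$split == "validation", ],
                         config = cfg)
  texts <- c("kwalpha visit", "kwalpha visit", "routine follow up")
  s <- predict(fit, texts)
  expect_true(all(s >= 0 & s <= 1))
  expect_identical(s, predict(fit, texts))
  expect_identical(s[1], s[2])        # identical inputs, identical outputs
  H <- note_representations(fit, texts)
  expect_identical(dim(H), c(3L, fit$encoder$dim))
  expect_identical(H[1, ], H[2, ])
  expect_true(all(is.finite(H)))
  # refitting with the same seed reproduces parameters exactly
  fit2 <- note_classifier(ch$primary[ch$primary$split == "train", ],
                          ch$primary[ch$primary$split == "validation", ],
                          config = cfg)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$history, fit2$history)
})

test_that("early stopping restores the best validation loss", {
  corpus <- separable_corpus(80, seed = 7)
  ch <- build_cohort(corpus$notes, corpus$medications, fixture_drugs(),
                     seed = 2)
  fit <- note_classifier(ch$primary[ch$primary$split == "train", ],
                         ch$primary[ch$primary$split == "validation", ],
                         config = train_config(max_epochs = 50, patience = 4,
                                               seed = 2))
  h <- fit$history
  expect_equal(fit$best_val_loss, min(h$val_loss))
  later <- h$val_loss[h$epoch > fit$best_epoch]
  if (length(later)) expect_true(all(fit$best_val_loss <= later + 1e-12))
  # patience semantics: training stops patience+1 epochs after the best
  expect_lte(nrow(h), fit$best_epoch + fit$config$patience + 1)
})

test_that("uninformative identical texts drive predictions to the prior", {
  n <- 60
  dat <- data.frame(text = rep("same note every time", n),
                    label = c(rep("TT-Yes", 0.7 * n), rep("TT-No", 0.3 * n)),
                    stringsAsFactors = FALSE)
  fit <- note_classifier(dat, dat,
                         config = train_config(max_epochs = 200,
                                               patience = 20, seed = 1))
  p <- predict(fit, "same note every time")
  expect_lt(abs(p - 0.7), 0.05)
})

test_that("degenerate training inputs raise errors", {
  dat <- data.frame(text = c("a b", "c d"), label = c("TT-Yes", "TT-Yes"),
                    stringsAsFactors = FALSE)
  expect_error(note_classifier(dat, dat), "single class")
  expect_error(train_config(patience = 10, max_epochs = 5), "patience")
  expect_error(train_config(learning_rate = -1))
})
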