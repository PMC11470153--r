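#' Delete a topic's keywords from text
#'
#' Removes every case-insensitive whole-word (or whole-phrase, longest
#' match first) occurrence of the given keywords, preserving the order of
#' the remaining tokens and collapsing the resulting whitespace. Idempotent.
#'
#' @param text character vector.
#' @param keywords character vector of keywords/phrases.
#' @return character vector of ablated texts.
#' @export
remove_topic_words <- function(text, keywords) {
  if (length(keywords) == 0) return(text)
  pat <- name_pattern(keywords)
  out <- gsub(pat, "", text, perl = TRUE, ignore.case = TRUE)
  trimws(gsub("\\s+", " ", out))
}

#' Fraction of notes mentioning a topic
#'
#' @param text character vector of note texts (non-empty).
#' @param keywords the topic's keyword set.
#' @return proportion of texts containing at least one keyword.
#' @export
topic_frequency <- function(text, keywords) {
  if (length(text) == 0) stop("test set must be non-empty")
  pat <- name_pattern(keywords)
  mean(grepl(pat, text, perl = TRUE, ignore.case = TRUE))
}

#' Topic-ablation feature importance
#'
#' For each topic independently, delete the topic's keywords from the test
#' inputs only (each ablation starts from the pristine test set), re-run
#' inference with the fitted model (no retraining), and record the decrease
#' in macro F1 relative to the unablated baseline. Because topics differ
#' widely in how often they are mentioned, the raw drop `delta_f1` is also
#' normalized by the topic's note-level frequency.
#'
#' @param model a fitted `note_clf` or `ms_clf`.
#' @param notes for a `note_clf`, a character vector of test note texts (or
#'   data.frame with `text`); for an `ms_clf`, a data.frame of test notes
#'   (patient_id, note_id, timestamp, text).
#' @param labels true binary labels: per note for `note_clf`, per patient
#'   (named by patient_id, or ordered as `unique(notes$patient_id)`) for
#'   `ms_clf`.
#' @param lexicon a `topic_lexicon`.
#' @param threshold hard-prediction threshold (default 0.5).
#' @return object of class `importance_scores`: a data.frame with columns
#'   `topic`, `delta_f1`, `frequency`, `normalized` (NA, flagged, when the
#'   topic never occurs), ordered as the lexicon, with the baseline macro F1
#'   as attribute `baseline_f1`.
#' @export
ablation_importance <- function(model, notes, labels, lexicon,
                                threshold = 0.5) {
  UseMethod("ablation_importance")
}

ablation_core <- function(texts, score_fun, labels, lexicon, threshold) {
  stopifnot(inherits(lexicon, "topic_lexicon"))
  y <- as_binary_label(labels)
  f1_of <- function(tx) {
    s <- score_fun(tx)
    unname(macro_metrics(y, as.integer(s >= threshold))["macro_f1"])
  }
  baseline <- f1_of(texts)
  rows <- lapply(names(lexicon), function(t) {
    kw <- lexicon[[t]]
    freq <- topic_frequency(texts, kw)
    ablated_f1 <- f1_of(remove_topic_words(texts, kw))
    delta <- baseline - ablated_f1
    data.frame(topic = t, delta_f1 = delta, frequency = freq,
               normalized = if (freq > 0) delta / freq else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_f1") <- baseline
  class(out) <- c("importance_scores", "data.frame")
  out
}

#' @rdname ablation_importance
#' @export
ablation_importance.note_clf <- function(model, notes, labels, lexicon,
                                         threshold = 0.5) {
  texts <- if (is.data.frame(notes)) notes$text else notes
  ablation_core(texts, function(tx) predict(model, tx, type = "prob"),
                labels, lexicon, threshold)
}

#' @rdname ablation_importance
#' @export
ablation_importance.ms_clf <- function(model, notes, labels, lexicon,
                                       threshold = 0.5) {
  stopifnot(is.data.frame(notes))
  ids <- unique(notes$patient_id)
  y <- if (!is.null(names(labels))) labels[ids] else labels
  score_fun <- function(tx) {
    nd <- notes
    nd$text <- tx
    unname(predict(model, nd, type = "prob")[ids])
  }
  ablation_core(notes$text, score_fun, y, lexicon, threshold)
}

#' @export
print.importance_scores <- function(x, ...) {
  cat(sprintf("Topic-ablation importance (baseline macro F1 %.3f)\n",
              attr(x, "baseline_f1")))
  df <- as.data.frame(x)
  df <- df[order(-df$delta_f1), ]
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.importance_scores <- function(x, normalized = FALSE, ...) {
  df <- as.data.frame(x)
  val <- if (normalized) df$normalized else df$delta_f1
  ord <- order(val)
  graphics::par(mar = c(4, 16, 2, 1))
  graphics::barplot(val[ord], names.arg = df$topic[ord], horiz = TRUE,
                    las = 1, cex.names = 0.7,
                    xlab = if (normalized) "delta F1 / frequency"
                           else "delta F1", ...)
  invisible(x)
}

#' Agreement between recovered and planted topic importances
#'
#' Validation harness for synthetic corpora: Spearman rank correlation
#' between the ablation importances (raw `delta_f1` and, separately, the
#' frequency-normalized score) and the planted per-topic effect sizes
#' |p_pos - p_neg|.
#'
#' @param scores an `importance_scores` object.
#' @param truth a `ground_truth` (from [generate_corpus()]) covering the
#'   same topics.
#' @return list with `spearman_delta`, `spearman_normalized`, `top_topic`
#'   (highest delta_f1), and `top_match` (TRUE if it is the largest planted
#'   effect).
#' @export
importance_recovery <- function(scores, truth) {
  stopifnot(inherits(scores, "importance_scores"),
            inherits(truth, "ground_truth"))
  eff <- truth$topic_effect_sizes
  common <- intersect(scores$topic, names(eff))
  if (length(common) < 3)
    stop("rank correlation needs at least 3 shared topics")
  s <- scores[match(common, scores$topic), ]
  e <- eff[common]
  list(
    spearman_delta = stats::cor(s$delta_f1, e, method = "spearman"),
    spearman_normalized = if (all(is.finite(s$normalized)))
      stats::cor(s$normalized, e, method = "spearman") else NA_real_,
    top_topic = s$topic[which.max(s$delta_f1)],
    top_match = s$topic[which.max(s$delta_f1)] == common[which.max(e)])
}
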