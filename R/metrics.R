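#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a uniformly chosen positive instance receives a
#' higher score than a uniformly chosen negative one, with ties counted one
#' half. Computed from midranks, which is algebraically identical to the
#' pairwise definition. A constant score vector therefore gives 0.5.
#'
#' @param labels binary labels ("TT-Yes"/"TT-No", logical, or 0/1); both
#'   classes must be present.
#' @param scores numeric scores, same length as labels.
#' @return AUROC in \[0,1\].
#' @export
auroc <- function(labels, scores) {
  y <- as_binary_label(labels)
  if (length(y) != length(scores)) stop("labels and scores lengths differ")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged F1, precision and recall for binary predictions
#'
#' Per-class precision, recall and F1 are computed for each of the two
#' classes and then averaged with equal weight (the arithmetic mean of the
#' per-class scores), so minority and majority classes count equally. A class
#' that is never predicted contributes precision 0; a class with no F1
#' denominator contributes F1 0.
#'
#' @param labels binary true labels (both classes present).
#' @param predictions binary predicted labels, same length.
#' @return named numeric vector `c(macro_f1, macro_precision, macro_recall)`.
#' @export
macro_metrics <- function(labels, predictions) {
  y <- as_binary_label(labels)
  p <- as_binary_label(predictions)
  if (length(y) == 0) stop("empty input")
  if (length(y) != length(p)) stop("labels and predictions lengths differ")
  if (length(unique(y)) < 2)
    stop("macro metrics need both classes among the true labels")
  per_class <- vapply(c(1, 0), function(cls) {
    tp <- sum(y == cls & p == cls)
    fp <- sum(y != cls & p == cls)
    fn <- sum(y == cls & p != cls)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(f1, prec, rec)
  }, numeric(3))
  out <- rowMeans(per_class)
  names(out) <- c("macro_f1", "macro_precision", "macro_recall")
  out
}

#' Evaluate scores against labels as a metric report
#'
#' Thresholds scores at `threshold` for the macro metrics and computes AUROC
#' from the raw scores.
#'
#' @param labels binary true labels.
#' @param scores numeric scores in \[0,1\].
#' @param threshold hard-prediction threshold (default 0.5).
#' @param run_seed optional seed identifying the training run.
#' @return object of class `metric_report`: named list with auroc, macro_f1,
#'   macro_precision, macro_recall, n_test, run_seed.
#' @export
metric_report <- function(labels, scores, threshold = 0.5, run_seed = NA) {
  y <- as_binary_label(labels)
  rep <- list(auroc = auroc(y, scores))
  mm <- macro_metrics(y, as.integer(scores >= threshold))
  rep <- c(rep, as.list(mm))
  rep$n_test <- length(y)
  rep$run_seed <- run_seed
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "AUROC %.3f | macro F1 %.3f | macro precision %.3f | macro recall %.3f (n = %d)\n",
    x$auroc, x$macro_f1, x$macro_precision, x$macro_recall, x$n_test))
  invisible(x)
}

#' Dummy baseline classifiers
#'
#' Three data-blind baselines used to rule out chance-level performance:
#' \describe{
#'   \item{prior}{always predicts the most frequent training class, with a
#'     constant score (the training positive fraction); ties in class
#'     frequency break toward the positive class.}
#'   \item{stratified}{predicts labels drawn with the training-class
#'     probabilities; scores are the 0/1 draws.}
#'   \item{uniform}{a fair coin; scores are Uniform(0,1).}
#' }
#' Stratified and uniform are deterministic given the seed.
#'
#' @param strategy one of `"prior"`, `"stratified"`, `"uniform"`.
#' @param train_labels binary labels of the training set (non-empty).
#' @param n_test number of test predictions to emit.
#' @param seed integer seed for the stochastic strategies.
#' @return list with `predictions` (0/1 integer) and `scores` (numeric).
#' @export
dummy_classifier <- function(strategy = c("prior", "stratified", "uniform"),
                             train_labels, n_test, seed = 1L) {
  strategy <- match.arg(strategy)
  y <- as_binary_label(train_labels)
  if (length(y) == 0) stop("train labels must be non-empty")
  stopifnot(n_test >= 1)
  q <- mean(y)
  switch(strategy,
    prior = {
      maj <- as.integer(q >= 0.5)
      list(predictions = rep(maj, n_test), scores = rep(q, n_test))
    },
    stratified = with_seed(seed, {
      pred <- stats::rbinom(n_test, 1, q)
      list(predictions = pred, scores = as.numeric(pred))
    }),
    uniform = with_seed(seed, {
      list(predictions = stats::rbinom(n_test, 1, 0.5),
           scores = stats::runif(n_test))
    })
  )
}

#' Median metrics over repeated training runs
#'
#' The reporting protocol: each metric's median is taken independently over
#' the per-run reports (midpoint convention for even counts).
#'
#' @param reports list of `metric_report` objects (>= 1).
#' @return object of class `run_summary`: list with `runs` (the input) and
#'   `median` (named numeric of per-metric medians).
#' @export
median_over_runs <- function(reports) {
  if (length(reports) == 0) stop("need at least one report")
  stopifnot(all(vapply(reports, inherits, TRUE, "metric_report")))
  metrics <- c("auroc", "macro_f1", "macro_precision", "macro_recall")
  med <- vapply(metrics, function(m)
    stats::median(vapply(reports, `[[`, 0, m)), 0)
  structure(list(runs = reports, median = med), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Median over", length(x$runs), "runs:\n")
  cat(sprintf(
    "  AUROC %.3f | macro F1 %.3f | macro precision %.3f | macro recall %.3f\n",
    x$median["auroc"], x$median["macro_f1"],
    x$median["macro_precision"], x$median["macro_recall"]))
  invisible(x)
}
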