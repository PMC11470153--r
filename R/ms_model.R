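#' Configuration for the hierarchical MS-n model
#'
#' MS-n integrates up to `n` notes per patient (typical settings 3, 5, 8,
#' 10): phase 1 fine-tunes the note-level model on every note with the
#' patient label broadcast to its notes; phase 2 freezes the encoder,
#' concatenates each patient's note representations and trains a
#' multilayer-perceptron head on the concatenation.
#'
#' @param n maximum notes per patient (>= 1).
#' @param selection which notes to keep when a patient has more than `n`:
#'   `"recent"` (the n most recent; default, matching the latest-note
#'   convention of the single-note model).
#' @param hidden width of the MLP head's hidden layer (default 64).
#' @return object of class `ms_config`.
#' @export
ms_config <- function(n = 5L, selection = c("recent"), hidden = 64L) {
  stopifnot(n >= 1, hidden >= 1)
  selection <- match.arg(selection)
  structure(list(n = as.integer(n), selection = selection,
                 hidden = as.integer(hidden)),
            class = "ms_config")
}

#' Broadcast patient labels to note-level instances
#'
#' Phase-1 data construction: every note becomes an independent training
#' instance carrying its patient's binary label, and inherits the patient's
#' split membership, so no note of a test patient ever enters phase-1
#' training.
#'
#' @param notes data.frame of notes (patient_id, note_id, timestamp, text).
#' @param patients data.frame with patient_id, label and (optionally) split.
#' @return the notes data.frame with `label` (and `split`) columns attached;
#'   one row per input note.
#' @export
broadcast_labels <- function(notes, patients) {
  idx <- match(notes$patient_id, patients$patient_id)
  if (any(is.na(idx)))
    stop("note(s) reference patients missing from the patient table")
  out <- notes
  out$label <- patients$label[idx]
  if (!is.null(patients$split)) out$split <- patients$split[idx]
  out
}

#' Concatenate one patient's note representations into a fixed-length vector
#'
#' Selects up to `n` notes (the most recent under the default policy),
#' orders the selected notes chronologically (oldest first), concatenates
#' their d-vectors into a length `n * d` vector, zero-pads missing blocks,
#' and records a mask of real vs padded blocks. Invariant to the input order
#' of the notes.
#'
#' @param reps numeric matrix of note representations (one row per note,
#'   d columns).
#' @param timestamps vector sortable as times, same length as rows of
#'   `reps`.
#' @param config an [ms_config()].
#' @return list with `vector` (length n*d), `mask` (logical length n, TRUE
#'   for real note blocks), and `d`.
#' @export
build_patient_representation <- function(reps, timestamps, config) {
  stopifnot(inherits(config, "ms_config"))
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
  k <- nrow(reps)
  if (k == 0) stop("need at least one note representation")
  if (length(timestamps) != k)
    stop("timestamps must match the number of representations")
  d <- ncol(reps)
  ord <- order(as.character(timestamps))      # chronological, stable
  keep <- utils::tail(ord, config$n)          # the n most recent, oldest first
  sel <- reps[keep, , drop = FALSE]
  m <- length(keep)
  vec <- numeric(config$n * d)
  vec[seq_len(m * d)] <- as.numeric(t(sel))   # block j = note j
  mask <- c(rep(TRUE, m), rep(FALSE, config$n - m))
  list(vector = vec, mask = mask, d = d)
}

# patients-by-(n*d) matrix of concatenated representations
patient_rep_matrix <- function(notes, rep_matrix, config) {
  ids <- unique(notes$patient_id)
  rows <- lapply(ids, function(p) {
    sel <- notes$patient_id == p
    build_patient_representation(rep_matrix[sel, , drop = FALSE],
                                 notes$timestamp[sel], config)$vector
  })
  Z <- do.call(rbind, rows)
  rownames(Z) <- ids
  Z
}

# MLP head forward/backward: z2 = W2' tanh(Z W1 + b1) + b2
head_forward <- function(p, Z) {
  A <- tanh(sweep(Z %*% p$W1, 2, p$b1, `+`))
  z <- drop(A %*% p$W2) + p$b2
  list(A = A, prob = stats::plogis(z))
}

#' Fit the hierarchical MS-n model
#'
#' The two-phase procedure: (1) broadcast patient labels to notes and
#' fine-tune the single-note classifier on all training-patient notes with
#' early stopping on the validation-patient notes; (2) extract note
#' representations under the phase-1 parameters, concatenate up to `n` per
#' patient (zero-padded), freeze the encoder, and train a one-hidden-layer
#' MLP head on the patient-level vectors, again with early stopping on
#' validation loss. Only the head's parameters change in phase 2.
#'
#' @param notes data.frame of masked notes (patient_id, note_id, timestamp,
#'   text).
#' @param patients data.frame with patient_id, label, split (train /
#'   validation / test).
#' @param config an [ms_config()].
#' @param train_cfg a [train_config()]; its seed drives both phases.
#' @param encoder an [embed_encoder()] for phase 1.
#' @return object of class `ms_clf`: list with `note_model` (the phase-1
#'   `note_clf`), `head` (MLP parameters), `config`, `train_cfg`,
#'   `head_history`, `best_epoch`.
#' @export
ms_classifier <- function(notes, patients, config = ms_config(),
                          train_cfg = train_config(),
                          encoder = embed_encoder()) {
  stopifnot(inherits(config, "ms_config"),
            inherits(train_cfg, "train_config"))
  if (is.null(patients$split))
    stop("patients must carry a split column (train/validation/test)")
  inst <- broadcast_labels(notes, patients)

  note_model <- note_classifier(
    train = inst[inst$split == "train", c("text", "label")],
    validation = inst[inst$split == "validation", c("text", "label")],
    encoder = encoder, config = train_cfg)

  # phase 2: frozen representations, patient-level head
  reps <- note_representations(note_model, notes$text)
  build <- function(which_split) {
    sel <- inst$split == which_split
    sub <- notes[sel, , drop = FALSE]
    Z <- patient_rep_matrix(sub, reps[sel, , drop = FALSE], config)
    y <- as_binary_label(
      patients$label[match(rownames(Z), patients$patient_id)])
    list(Z = Z, y = y)
  }
  tr <- build("train"); va <- build("validation")
  width <- config$n * encoder$dim
  stopifnot(ncol(tr$Z) == width)
  n_tr <- nrow(tr$Z)

  head <- with_seed(train_cfg$seed + 1L, list(
    W1 = matrix(stats::rnorm(width * config$hidden, sd = 1 / sqrt(width)),
                width, config$hidden),
    b1 = numeric(config$hidden),
    W2 = stats::rnorm(config$hidden, sd = 0.1),
    b2 = 0))

  forward <- function(p) {
    fw <- head_forward(p, tr$Z)
    pr <- clamp_p(fw$prob)
    g <- (pr - tr$y) / n_tr
    dA <- outer(g, p$W2) * (1 - fw$A^2)
    list(loss = binary_ce(pr, tr$y),
         grads = list(W1 = crossprod(tr$Z, dA),
                      b1 = colSums(dA),
                      W2 = drop(crossprod(fw$A, g)),
                      b2 = sum(g)))
  }
  val_loss <- function(p) binary_ce(head_forward(p, va$Z)$prob, va$y)

  fit <- train_loop(head, forward, val_loss, train_cfg)
  structure(list(note_model = note_model, head = fit$params,
                 config = config, train_cfg = train_cfg,
                 head_history = fit$history, best_epoch = fit$best_epoch,
                 best_val_loss = fit$best_val_loss),
            class = "ms_clf")
}

#' Predict patient-level scores from a fitted MS-n model
#'
#' Re-encodes the given notes with the frozen phase-1 encoder, rebuilds the
#' concatenated patient representations, and applies the MLP head.
#'
#' @param object an `ms_clf`.
#' @param newdata data.frame of notes (patient_id, note_id, timestamp,
#'   text) for the patients to score.
#' @param type `"prob"` (default) or `"class"`.
#' @param ... unused.
#' @return named numeric (or integer) vector, one entry per patient.
#' @export
predict.ms_clf <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  reps <- note_representations(object$note_model, newdata$text)
  Z <- patient_rep_matrix(newdata, reps, object$config)
  p <- head_forward(object$head, Z)$prob
  names(p) <- rownames(Z)
  if (type == "class") {
    cl <- as.integer(p >= 0.5); names(cl) <- names(p); cl
  } else p
}

#' @export
print.ms_clf <- function(x, ...) {
  cat(sprintf("MS-%d hierarchical classifier (d = %d, head hidden = %d)\n",
              x$config$n, x$note_model$encoder$dim, x$config$hidden))
  cat(sprintf("  phase-1 best epoch %d | phase-2 best epoch %d (val loss %.4f)\n",
              x$note_model$best_epoch, x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
summary.ms_clf <- function(object, ...) {
  print(object)
  cat("Phase-2 head history (last 5 epochs):\n")
  print(utils::tail(object$head_history, 5), row.names = FALSE)
  invisible(object)
}
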