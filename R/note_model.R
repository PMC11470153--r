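#' Tokenize text and truncate to a maximum input length
#'
#' Word-level tokenization: lower-case, strip non-alphanumeric characters,
#' split on whitespace, keep the leading `max_tokens` tokens (the encoder
#' input-length limit, default 512). Empty text yields a single unknown
#' token rather than an error.
#'
#' @param text character vector.
#' @param max_tokens maximum tokens kept per text (>= 1).
#' @return list of character token vectors, one per input text.
#' @export
tokenize_truncate <- function(text, max_tokens = 512L) {
  stopifnot(max_tokens >= 1)
  clean <- tolower(text)
  clean <- gsub("[^a-z0-9]+", " ", clean)
  toks <- strsplit(trimws(clean), " ", fixed = TRUE)
  lapply(toks, function(t) {
    t <- t[nzchar(t)]
    if (length(t) == 0) return("<unk>")
    utils::head(t, max_tokens)
  })
}

#' Cross-entropy loss for one prediction
#'
#' Returns `-log p(label)` for a predicted class distribution. Probabilities
#' are clamped at 1e-12 for numerical safety, so a zero probability on the
#' true class yields a large finite loss.
#'
#' @param probabilities numeric class distribution (sums to 1).
#' @param label the true class: an index into `probabilities` or an element
#'   of its names.
#' @return nonnegative loss value.
#' @export
cross_entropy <- function(probabilities, label) {
  if (abs(sum(probabilities) - 1) > 1e-6)
    stop("probabilities must sum to 1")
  p <- if (is.character(label)) probabilities[[label]]
       else probabilities[[as.integer(label)]]
  -log(max(p, 1e-12))
}

#' Training configuration for the note and MS-n models
#'
#' @param max_tokens encoder input-length limit (default 512).
#' @param max_epochs maximum training epochs.
#' @param patience early stopping: training halts once the validation loss
#'   has failed to improve for more than `patience` consecutive epochs
#'   (patience 0 stops at the first non-improvement); the best-validation
#'   parameters are restored. The default is generous (60) because on
#'   weak-signal corpora the momentum dynamics pass through long
#'   low-improvement stretches before the lexical signal is found; a short
#'   patience stops inside them.
#' @param learning_rate step size of the full-batch momentum gradient
#'   descent. The mean-pooled features are small (each token contributes
#'   1/length), so the useful range is well above typical mini-batch values;
#'   the default 3 is stable across corpus sizes.
#' @param momentum classical momentum coefficient (default 0.9).
#' @param weight_decay optional L2 weight decay on embedding and weight
#'   tensors (not biases); default 0.
#' @param n_runs number of repeated runs in the reporting protocol
#'   (default 5).
#' @param seed integer seed; (data, config, seed) reproduces training.
#' @return object of class `train_config`.
#' @export
train_config <- function(max_tokens = 512L, max_epochs = 400L,
                         patience = 60L, learning_rate = 3,
                         momentum = 0.95, weight_decay = 0,
                         n_runs = 5L, seed = 1L) {
  stopifnot(max_tokens >= 1, max_epochs >= 1, n_runs >= 1,
            learning_rate > 0, momentum >= 0, momentum < 1,
            weight_decay >= 0)
  if (!(patience >= 0 && patience < max_epochs))
    stop("patience must satisfy 0 <= patience < max_epochs")
  structure(list(max_tokens = as.integer(max_tokens),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 momentum = momentum,
                 weight_decay = weight_decay,
                 n_runs = as.integer(n_runs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' The default trainable encoder: word embeddings with mean pooling
#'
#' A note is encoded as the mean of its token embeddings, a d-dimensional
#' vector; embeddings are trained jointly with the classification head
#' (the "fine-tuning" of this small encoder). Any large pre-trained backend
#' can be substituted provided it satisfies the same contract: a
#' deterministic map from a token sequence to a fixed-length vector.
#'
#' @param dim embedding dimension d (default 32).
#' @param init_sd standard deviation of the Gaussian embedding
#'   initialization.
#' @return object of class `embed_encoder`.
#' @export
embed_encoder <- function(dim = 32L, init_sd = 0.1) {
  stopifnot(dim >= 1, init_sd > 0)
  structure(list(dim = as.integer(dim), init_sd = init_sd, trainable = TRUE),
            class = "embed_encoder")
}

# ---- internal numerics ----

# documents-by-vocabulary matrix of row-normalized counts; OOV -> "<unk>"
doc_matrix <- function(token_lists, vocab) {
  idx <- lapply(token_lists, function(t) {
    i <- match(t, vocab)
    i[is.na(i)] <- 1L  # vocab[1] is "<unk>"
    i
  })
  lens <- lengths(idx)
  m <- Matrix::sparseMatrix(
    i = rep.int(seq_along(idx), lens),
    j = unlist(idx),
    x = rep.int(1 / lens, lens),
    dims = c(length(idx), length(vocab)))
  m
}

clamp_p <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

binary_ce <- function(p, y) {
  p <- clamp_p(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# full-batch gradient descent with classical momentum; weight decay (when
# nonzero) applies to weight tensors, not biases
momentum_step <- function(params, grads, state, lr, momentum, weight_decay) {
  for (k in names(params)) {
    g <- grads[[k]]
    if (weight_decay > 0 && !(k %in% c("b", "b1", "b2")))
      g <- g + weight_decay * params[[k]]
    state[[k]] <- momentum * state[[k]] - lr * g
    params[[k]] <- params[[k]] + state[[k]]
  }
  list(params = params, state = state)
}

# generic early-stopped training loop; forward(params) -> list(loss, grads),
# val_loss(params) -> numeric
train_loop <- function(params, forward, val_loss, config) {
  st <- lapply(params, function(p) p * 0)
  best <- list(val = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    fw <- forward(params)
    if (!is.finite(fw$loss))
      stop("non-finite training loss at epoch ", epoch,
           " (learning rate too high or degenerate input)")
    up <- momentum_step(params, fw$grads, st, config$learning_rate,
                        config$momentum, config$weight_decay)
    params <- up$params; st <- up$state
    vl <- val_loss(params)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = fw$loss,
                                   val_loss = vl))
    if (vl < best$val - 1e-9) {
      best <- list(val = vl, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > config$patience) break
    }
  }
  list(params = best$params, best_epoch = best$epoch,
       best_val_loss = best$val, history = hist)
}

#' Train the single-note binary classifier
#'
#' Fits the note-level model: tokenize and truncate each note, encode with
#' the trainable mean-pooled embedding encoder, and optimize a logistic
#' classification head jointly with the embeddings by full-batch Adam under
#' the cross-entropy loss, with early stopping on the validation loss (the
#' best-validation parameters are restored). Deterministic given the config
#' seed.
#'
#' @param train data.frame with columns `text` and `label` (both classes
#'   must be present).
#' @param validation data.frame with columns `text` and `label`.
#' @param encoder an [embed_encoder()].
#' @param config a [train_config()].
#' @return object of class `note_clf` with elements `vocab`, `params`
#'   (embedding matrix E, head weights w, bias b), `history` (per-epoch
#'   train/validation loss), `best_epoch`, `best_val_loss`, `encoder`,
#'   `config`.
#' @seealso [predict.note_clf()], [note_representations()]
#' @export
note_classifier <- function(train, validation, encoder = embed_encoder(),
                            config = train_config()) {
  stopifnot(is.data.frame(train), is.data.frame(validation),
            inherits(encoder, "embed_encoder"),
            inherits(config, "train_config"))
  if (nrow(train) == 0 || nrow(validation) == 0)
    stop("train and validation sets must be non-empty")
  y_tr <- as_binary_label(train$label)
  y_va <- as_binary_label(validation$label)
  if (length(unique(y_tr)) < 2)
    stop("training split contains a single class; cannot fit a classifier")

  toks_tr <- tokenize_truncate(train$text, config$max_tokens)
  toks_va <- tokenize_truncate(validation$text, config$max_tokens)
  vocab <- c("<unk>", sort(setdiff(unique(unlist(toks_tr)), "<unk>")))
  X_tr <- doc_matrix(toks_tr, vocab)
  X_va <- doc_matrix(toks_va, vocab)
  d <- encoder$dim
  n_tr <- nrow(X_tr)

  # head init sd 0.5: a non-vanishing head is needed for gradient to reach
  # the embeddings early (the bilinear saddle is slow to escape otherwise)
  params <- with_seed(config$seed, list(
    E = matrix(stats::rnorm(length(vocab) * d, sd = encoder$init_sd),
               length(vocab), d),
    w = stats::rnorm(d, sd = 0.5),
    b = 0))

  forward <- function(p) {
    H <- as.matrix(X_tr %*% p$E)
    z <- drop(H %*% p$w) + p$b
    pr <- clamp_p(stats::plogis(z))
    g <- (pr - y_tr) / n_tr
    dH <- outer(g, p$w)
    list(loss = binary_ce(pr, y_tr),
         grads = list(E = as.matrix(Matrix::crossprod(X_tr, dH)),
                      w = drop(crossprod(H, g)),
                      b = sum(g)))
  }
  val_loss <- function(p) {
    z <- drop(as.matrix(X_va %*% p$E) %*% p$w) + p$b
    binary_ce(stats::plogis(z), y_va)
  }

  fit <- train_loop(params, forward, val_loss, config)
  structure(list(vocab = vocab, params = fit$params,
                 history = fit$history, best_epoch = fit$best_epoch,
                 best_val_loss = fit$best_val_loss,
                 encoder = encoder, config = config,
                 n_train = n_tr, n_validation = nrow(X_va)),
            class = "note_clf")
}

#' Predict from a fitted note classifier
#'
#' @param object a `note_clf`.
#' @param newdata character vector of note texts, or a data.frame with a
#'   `text` column.
#' @param type `"prob"` for positive-class probabilities, `"class"` for
#'   0/1 predictions at threshold 0.5, `"representation"` for the pooled
#'   d-dimensional note representations (one row per note).
#' @param ... unused.
#' @return numeric vector, integer vector, or numeric matrix per `type`.
#' @export
predict.note_clf <- function(object, newdata,
                             type = c("prob", "class", "representation"),
                             ...) {
  type <- match.arg(type)
  text <- if (is.data.frame(newdata)) newdata$text else newdata
  toks <- tokenize_truncate(text, object$config$max_tokens)
  X <- doc_matrix(toks, object$vocab)
  H <- as.matrix(X %*% object$params$E)
  if (type == "representation") {
    rownames(H) <- NULL
    return(H)
  }
  p <- stats::plogis(drop(H %*% object$params$w) + object$params$b)
  if (type == "class") as.integer(p >= 0.5) else p
}

#' Extract pooled note representations
#'
#' The fixed-length (d-dimensional) note representations under the fitted
#' encoder parameters — the phase-1 output consumed by the hierarchical MS-n
#' model.
#'
#' @param model a fitted `note_clf`.
#' @param text note texts (character vector or data.frame with `text`).
#' @return numeric matrix, one row per note.
#' @export
note_representations <- function(model, text) {
  stopifnot(inherits(model, "note_clf"))
  predict(model, text, type = "representation")
}

#' @export
print.note_clf <- function(x, ...) {
  cat("Single-note classifier (bag-of-embeddings encoder, d =",
      x$encoder$dim, ")\n")
  cat(sprintf("  vocab %d | trained on %d notes | best epoch %d (val loss %.4f)\n",
              length(x$vocab), x$n_train, x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
summary.note_clf <- function(object, ...) {
  print(object)
  cat("Training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
plot.note_clf <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"),
                   col = c("black", "red3"), lty = 1, bty = "n")
  invisible(x)
}
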