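#' Specification for a synthetic social-work-note corpus
#'
#' Defines the statistical structure of a generated corpus: label prevalence,
#' the per-patient note-count distribution, per-topic class-dependent
#' keyword-inclusion probabilities, the drug-mention rate, and the background
#' text model. Defaults mirror the study conditions of the real cohort:
#' 2496 patients, 70% TT-Yes prevalence, a heavy-tailed note-count
#' distribution (sample mode 1-2, median about 11, mean about 22), and drug
#' mentions in under 10% of notes.
#'
#' @param n_patients number of patients.
#' @param prevalence probability a patient is TT-Yes, in (0,1).
#' @param note_count_params list with `size` and `mu`: per-patient note count
#'   is `1 + NegBinomial(size, mu)` (support >= 1). `mu = 0` is the
#'   degenerate single-note distribution.
#' @param topic_effects named list, one entry per topic, each a numeric pair
#'   `c(p_pos, p_neg)`: the probability a note of a TT-Yes (resp. TT-No)
#'   patient contains that topic's keywords. See [default_topic_effects()].
#' @param drug_mention_rate probability a note carries a drug-name sentence,
#'   in \[0,1).
#' @param background_vocab_size number of distinct background filler tokens.
#' @param mean_note_length mean number of background tokens per note
#'   (Poisson, floored at 10).
#' @param seed integer seed; the same spec and seed reproduce the corpus
#'   byte for byte.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients = 2496,
                           prevalence = 0.7,
                           note_count_params = list(size = 0.55, mu = 21),
                           topic_effects = NULL,
                           drug_mention_rate = 0.08,
                           background_vocab_size = 500,
                           mean_note_length = 80,
                           seed = 1L) {
  stopifnot(n_patients >= 1)
  if (!(prevalence > 0 && prevalence < 1)) stop("prevalence must be in (0,1)")
  if (!(drug_mention_rate >= 0 && drug_mention_rate < 1))
    stop("drug_mention_rate must be in [0,1)")
  validate_note_count_params(note_count_params)
  if (!is.null(topic_effects)) validate_topic_effects(topic_effects)
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = prevalence,
                 note_count_params = note_count_params,
                 topic_effects = topic_effects,
                 drug_mention_rate = drug_mention_rate,
                 background_vocab_size = as.integer(background_vocab_size),
                 mean_note_length = mean_note_length,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

validate_note_count_params <- function(p) {
  if (!is.list(p) || is.null(p$size) || is.null(p$mu) ||
      !is.finite(p$size) || !is.finite(p$mu) || p$size <= 0 || p$mu < 0)
    stop("invalid note-count distribution parameters: need size > 0, mu >= 0")
  invisible(p)
}

validate_topic_effects <- function(te) {
  if (!is.list(te) || length(te) == 0 || is.null(names(te)))
    stop("topic_effects must be a named list of c(p_pos, p_neg) pairs")
  for (t in names(te)) {
    pr <- te[[t]]
    if (length(pr) != 2 || any(!is.finite(pr)) || any(pr < 0) || any(pr > 1))
      stop("topic_effects[['", t, "']] must be two probabilities in [0,1]")
  }
  invisible(te)
}

#' Default per-topic marginal keyword frequencies
#'
#' Note-level frequencies spanning the range observed in real social work
#' notes: ubiquitous topics such as living condition/social support appear in
#' about 96% of notes while risk-of-death language appears in about 10%.
#'
#' @return named numeric vector over the [sdoh_topics()] topic names.
#' @export
default_topic_frequencies <- function() {
  c("Mental health" = 0.80,
    "Family" = 0.85,
    "Consultation/Appointment" = 0.70,
    "Group session" = 0.25,
    "Risk of death" = 0.10,
    "Clinician/Hospital/Medication" = 0.90,
    "Living condition/Lifestyle/Social support" = 0.96,
    "Telephone encounter/Online communication" = 0.50,
    "Abuse history" = 0.15,
    "Insurance/Income" = 0.40)
}

#' Build class-dependent topic inclusion probabilities
#'
#' For each topic with marginal note-level frequency f and planted effect
#' delta = p_pos - p_neg, sets p_pos = f + (1 - prevalence) * delta and
#' p_neg = f - prevalence * delta (clipped to \[0,1\]), so the marginal
#' frequency prevalence * p_pos + (1 - prevalence) * p_neg stays at f.
#'
#' @param lexicon a `topic_lexicon`; effects are built for its topics.
#' @param frequencies named marginal frequencies per topic
#'   (default [default_topic_frequencies()] where names match, else 0.5).
#' @param effect planted effect size(s) delta, recycled over topics; 0 gives
#'   a null corpus with no class signal.
#' @param prevalence TT-Yes prevalence used for the marginal decomposition.
#' @return named list of `c(p_pos, p_neg)` pairs.
#' @export
default_topic_effects <- function(lexicon, frequencies = NULL, effect = 0.1,
                                  prevalence = 0.7) {
  nms <- names(lexicon)
  if (is.null(frequencies)) {
    def <- default_topic_frequencies()
    frequencies <- ifelse(nms %in% names(def), def[nms], 0.5)
    names(frequencies) <- nms
  }
  frequencies <- frequencies[nms]
  if (any(is.na(frequencies))) stop("frequencies must cover every topic")
  effect <- rep_len(effect, length(nms))
  te <- lapply(seq_along(nms), function(i) {
    f <- frequencies[[i]]; d <- effect[[i]]
    c(p_pos = min(1, max(0, f + (1 - prevalence) * d)),
      p_neg = min(1, max(0, f - prevalence * d)))
  })
  names(te) <- nms
  te
}

#' Sample per-patient note counts
#'
#' Draws from the shifted negative binomial `1 + NB(size, mu)` configured in
#' the spec. With the default parameters (size 0.55, mu 21) a sample of 2000
#' patients has mode 1-2, median near 11 and mean near 22, the heavy-tailed
#' shape of real per-patient note counts.
#'
#' @param spec a `synthetic_spec`.
#' @param n number of patients to draw for.
#' @param seed seed used for the draw (default the spec's seed); `NULL` uses
#'   the current RNG stream.
#' @return integer vector of length `n`, all values >= 1.
#' @export
sample_note_counts <- function(spec, n, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"), n >= 1)
  p <- validate_note_count_params(spec$note_count_params)
  with_seed(seed, {
    if (p$mu == 0) rep(1L, n)
    else 1L + stats::rnbinom(n, size = p$size, mu = p$mu)
  })
}

#' Generate a synthetic note corpus with planted SDOH signal
#'
#' Emulates the structure of a social-work-note corpus: each patient receives
#' a Bernoulli(prevalence) TT-Yes/TT-No label, a heavy-tailed number of notes
#' with strictly increasing timestamps, and notes composed of background
#' filler tokens into which, independently per note and topic, one of the
#' topic's keywords is inserted with probability `p_pos` or `p_neg` according
#' to the patient label. A fraction `drug_mention_rate` of notes carries a
#' drug sentence ("<Drug> was administered to the patient.") naming one of
#' the patient's own medications. Medication tables are consistent with
#' labels: every TT-Yes patient has at least one targeted-lexicon drug and no
#' TT-No patient has any.
#'
#' @param spec a `synthetic_spec`. If `spec$topic_effects` is `NULL`,
#'   [default_topic_effects()] over the lexicon is used.
#' @param lexicon a `topic_lexicon` (default [sdoh_topics()]).
#' @param drugs a `drug_lexicon` (default [drug_lexicon()]).
#' @return object of class `note_corpus`: a list with
#'   \describe{
#'     \item{notes}{data.frame of patient_id, note_id, timestamp (ISO-8601),
#'       text}
#'     \item{medications}{data.frame of patient_id, drug_name}
#'     \item{truth}{`ground_truth`: patient_labels (named character) and
#'       topic_effect_sizes (named |p_pos - p_neg|)}
#'     \item{spec}{the generating spec (with effects resolved)}
#'   }
#' @export
generate_corpus <- function(spec, lexicon = sdoh_topics(),
                            drugs = drug_lexicon()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!inherits(lexicon, "topic_lexicon") || length(lexicon) == 0)
    stop("lexicon must be a non-empty topic_lexicon")
  te <- spec$topic_effects
  if (is.null(te))
    te <- default_topic_effects(lexicon, prevalence = spec$prevalence)
  validate_topic_effects(te)
  missing <- setdiff(names(lexicon), names(te))
  if (length(missing))
    stop("topic_effects missing topic(s): ", paste(missing, collapse = ", "))
  te <- te[names(lexicon)]
  spec$topic_effects <- te

  nontargeted <- setdiff(drugs$maskable, drugs$targeted)
  if (length(nontargeted) == 0)
    stop("drug lexicon needs at least one non-targeted maskable drug for TT-No patients")
  vocab <- sprintf("w%04d", seq_len(spec$background_vocab_size))

  with_seed(spec$seed, {
    n <- spec$n_patients
    pid <- sprintf("P%05d", seq_len(n))
    labels <- ifelse(stats::rbinom(n, 1, spec$prevalence) == 1,
                     "TT-Yes", "TT-No")
    names(labels) <- pid
    counts <- sample_note_counts(spec, n, seed = NULL)

    # medications, consistent with labels
    meds <- lapply(seq_len(n), function(i) {
      if (labels[i] == "TT-Yes") {
        m <- sample(drugs$targeted, 1)
        if (stats::runif(1) < 0.5) m <- c(m, sample(nontargeted, 1))
      } else {
        m <- sample(nontargeted, 1 + stats::rbinom(1, 1, 0.5))
      }
      unique(m)
    })
    medications <- data.frame(
      patient_id = rep(pid, lengths(meds)),
      drug_name = unlist(meds),
      stringsAsFactors = FALSE)

    # note skeleton
    total <- sum(counts)
    note_pid <- rep(pid, counts)
    note_lab <- rep(labels, counts)
    note_id <- sprintf("%s-N%03d", note_pid,
                       unlist(lapply(counts, seq_len)))
    # strictly increasing timestamps per patient: random start, positive gaps
    start <- as.Date("2012-01-01") + sample.int(2000, n, replace = TRUE)
    gaps <- 1L + sample.int(30, total, replace = TRUE)
    ends <- cumsum(counts)
    begins <- c(1L, utils::head(ends, -1L) + 1L)
    dates <- as.Date(unlist(lapply(seq_len(n), function(i) {
      start[i] + cumsum(gaps[begins[i]:ends[i]])
    })), origin = "1970-01-01")
    timestamp <- format(dates, "%Y-%m-%dT09:00:00")

    # background tokens
    lens <- pmax(10L, stats::rpois(total, spec$mean_note_length))
    bg <- sample(vocab, sum(lens), replace = TRUE)
    bg_split <- split(bg, rep.int(seq_len(total), lens))

    # per-topic inclusion: one randomly chosen keyword phrase when included
    pos <- note_lab == "TT-Yes"
    phrase <- vector("list", total)
    for (t in names(lexicon)) {
      p_note <- ifelse(pos, te[[t]][1], te[[t]][2])
      inc <- stats::runif(total) < p_note
      if (any(inc)) {
        kw <- sample(lexicon[[t]], sum(inc), replace = TRUE)
        idx <- which(inc)
        for (j in seq_along(idx))
          phrase[[idx[j]]] <- c(phrase[[idx[j]]], kw[j])
      }
    }

    # drug mentions drawn from the patient's own medication list
    has_drug <- stats::runif(total) < spec$drug_mention_rate
    med_of <- meds[match(note_pid, pid)]
    drug_sentence <- character(total)
    if (any(has_drug)) {
      di <- which(has_drug)
      dn <- vapply(med_of[di], function(m) sample(m, 1)[[1]], "")
      drug_sentence[di] <- sprintf(
        "%s was administered to the patient.",
        paste0(toupper(substr(dn, 1, 1)), substring(dn, 2)))
    }

    text <- vapply(seq_len(total), function(i) {
      units <- c(bg_split[[i]], phrase[[i]])
      s <- paste(sample(units), collapse = " ")
      if (has_drug[i]) s <- paste(s, drug_sentence[i])
      s
    }, "")

    notes <- data.frame(patient_id = note_pid, note_id = note_id,
                        timestamp = timestamp, text = text,
                        stringsAsFactors = FALSE)
    effects <- vapply(te, function(pr) abs(pr[1] - pr[2]), 0)
    truth <- structure(list(patient_labels = labels,
                            topic_effect_sizes = effects),
                       class = "ground_truth")
    structure(list(notes = notes, medications = medications,
                   truth = truth, spec = spec),
              class = "note_corpus")
  })
}

#' @export
print.note_corpus <- function(x, ...) {
  n <- length(x$truth$patient_labels)
  cat("Synthetic note corpus:", n, "patients,", nrow(x$notes), "notes\n")
  cat(sprintf("  TT-Yes prevalence: %.3f (spec %.2f)\n",
              mean(x$truth$patient_labels == "TT-Yes"), x$spec$prevalence))
  cat(sprintf("  notes per patient: median %d, mean %.1f\n",
              as.integer(stats::median(table(x$notes$patient_id))),
              nrow(x$notes) / n))
  invisible(x)
}

#' Write a corpus to disk in interchange formats
#'
#' Notes as JSON-lines (one record per line), medications as CSV, and ground
#' truth as JSON.
#'
#' @param corpus a `note_corpus`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "note_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "notes.jsonl"), "w")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus$notes))) {
    writeLines(jsonlite::toJSON(as.list(corpus$notes[i, ]),
                                auto_unbox = TRUE), con)
  }
  utils::write.csv(corpus$medications,
                   file.path(dir, "medications.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(patient_labels = as.list(corpus$truth$patient_labels),
         topic_effect_sizes = as.list(corpus$truth$topic_effect_sizes)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read notes from a JSON-lines file
#'
#' @param path file with one JSON note record per line
#'   (patient_id, note_id, timestamp, text).
#' @return data.frame of notes.
#' @export
read_notes_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(patient_id = vapply(recs, `[[`, "", "patient_id"),
             note_id = vapply(recs, `[[`, "", "note_id"),
             timestamp = vapply(recs, `[[`, "", "timestamp"),
             text = vapply(recs, `[[`, "", "text"),
             stringsAsFactors = FALSE)
}

#' Read a patient medication table from CSV
#'
#' @param path CSV with columns patient_id, drug_name.
#' @return data.frame.
#' @export
read_medications <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "drug_name") %in% names(df)))
    stop("medication table needs patient_id and drug_name columns")
  df
}
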