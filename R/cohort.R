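#' Label a patient from their medication list
#'
#' A patient is TT-Yes if any of their medications matches a targeted-therapy
#' drug name (case-insensitive exact name match), TT-No otherwise. An empty
#' medication list is valid and yields TT-No.
#'
#' @param medications character vector of drug names for one patient.
#' @param lexicon a `drug_lexicon` with a non-empty `targeted` set.
#' @return `"TT-Yes"` or `"TT-No"`.
#' @export
assign_label <- function(medications, lexicon) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  if (length(lexicon$targeted) == 0) stop("targeted set must be non-empty")
  if (length(medications) && any(tolower(trimws(medications)) %in%
                                 lexicon$targeted)) "TT-Yes" else "TT-No"
}

#' Mask drug names in note text
#'
#' Replaces every case-insensitive, whole-word occurrence of a maskable drug
#' name with the literal token `"drug"`, leaving all other characters
#' (including adjacent punctuation) unchanged. Multi-word names are matched
#' longest-first so a phrase wins over its components. Masking is idempotent
#' and its output contains no maskable name.
#'
#' @param text character vector of note texts.
#' @param lexicon a `drug_lexicon`; the `maskable` set is masked.
#' @return character vector of masked texts.
#' @export
mask_drugs <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  if (length(lexicon$maskable) == 0) return(text)
  pat <- name_pattern(lexicon$maskable)
  gsub(pat, "drug", text, perl = TRUE, ignore.case = TRUE)
}

#' Select the primary (latest, longest) note of a patient
#'
#' Restricts to the patient's most recent calendar day with notes, then takes
#' the longest note of that day by whitespace token count; remaining ties are
#' broken toward the lexicographically larger note_id. Deterministic.
#'
#' @param notes data.frame of one patient's notes with columns `note_id`,
#'   `timestamp` (ISO-8601 or Date-coercible) and `text`.
#' @return the selected one-row data.frame.
#' @export
select_primary_note <- function(notes) {
  if (is.null(notes) || nrow(notes) == 0)
    stop("patient has no notes and must be excluded from the cohort")
  day <- as.Date(substr(notes$timestamp, 1, 10))
  cand <- notes[day == max(day), , drop = FALSE]
  len <- count_tokens(cand$text)
  best <- which(len == max(len))
  if (length(best) > 1)
    best <- best[order(cand$note_id[best], decreasing = TRUE)[1]]
  cand[best[1], , drop = FALSE]
}

#' Patient-level train/validation/test split
#'
#' Randomly partitions patients in the given ratio (default 8:1:1). Sizes are
#' `floor(r_train * N)`, `floor(r_val * N)` and the remainder, so the test
#' set absorbs rounding and is never smaller than nominal. The split is at
#' patient level: no patient appears in two splits.
#'
#' @param patient_ids vector of unique patient ids (N >= 3).
#' @param ratio positive weights for train/validation/test (default c(8,1,1)).
#' @param seed integer seed; the same seed reproduces the assignment.
#' @return named character vector mapping patient id to
#'   `"train"`, `"validation"` or `"test"`, with the seed as an attribute.
#' @export
split_patients <- function(patient_ids, ratio = c(8, 1, 1), seed = 1L) {
  ids <- as.character(patient_ids)
  if (anyDuplicated(ids)) stop("patient ids must be unique")
  n <- length(ids)
  if (n < 3) stop("need at least 3 patients to form three splits")
  stopifnot(length(ratio) == 3, all(ratio > 0))
  w <- ratio / sum(ratio)
  n_train <- floor(w[1] * n)
  n_val <- floor(w[2] * n)
  perm <- with_seed(seed, sample(ids))
  split <- rep("test", n)
  split[seq_len(n_train)] <- "train"
  if (n_val > 0) split[n_train + seq_len(n_val)] <- "validation"
  out <- split[match(ids, perm)]
  names(out) <- ids
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Notes that never mention a drug
#'
#' Returns exactly the notes whose raw (pre-masking) text contains no
#' maskable drug name, for evaluating models on drug-free text.
#'
#' @param notes data.frame of notes with a `text` column.
#' @param lexicon a `drug_lexicon`.
#' @return the filtered data.frame.
#' @export
drug_free_subset <- function(notes, lexicon) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  if (nrow(notes) == 0) return(notes)
  pat <- name_pattern(lexicon$maskable)
  notes[!grepl(pat, notes$text, perl = TRUE, ignore.case = TRUE), ,
        drop = FALSE]
}

#' Build the labeled, masked, split modeling dataset
#'
#' The full cohort pipeline: label each patient from the medication table,
#' mask every maskable drug name in all note text, split patients 8:1:1
#' (train/validation/test) at patient level, and select each patient's
#' primary (latest, longest) note. Patients without notes are excluded.
#'
#' @param notes data.frame of notes (patient_id, note_id, timestamp, text).
#' @param medications data.frame (patient_id, drug_name).
#' @param lexicon a `drug_lexicon`.
#' @param ratio split ratio, default c(8, 1, 1).
#' @param seed split seed.
#' @return object of class `cohort`: list with
#'   \describe{
#'     \item{patients}{data.frame patient_id, label, split, n_notes}
#'     \item{notes}{all notes with masked text plus label and split columns}
#'     \item{primary}{one masked primary note per patient (patient_id, text,
#'       label, split)}
#'   }
#' @export
build_cohort <- function(notes, medications, lexicon,
                         ratio = c(8, 1, 1), seed = 1L) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  if (anyDuplicated(notes[c("patient_id", "note_id")]))
    stop("(patient_id, note_id) pairs must be unique")
  ids <- sort(unique(notes$patient_id))
  meds_by <- split(medications$drug_name, medications$patient_id)
  label <- vapply(ids, function(p)
    assign_label(meds_by[[p]], lexicon), "")
  split_map <- split_patients(ids, ratio = ratio, seed = seed)

  masked <- notes
  masked$text <- mask_drugs(masked$text, lexicon)
  masked$label <- label[match(masked$patient_id, ids)]
  masked$split <- unname(split_map[masked$patient_id])

  by_pat <- split(masked, masked$patient_id)
  primary <- do.call(rbind, lapply(by_pat, select_primary_note))
  primary <- primary[match(ids, primary$patient_id),
                     c("patient_id", "text", "label", "split")]
  rownames(primary) <- NULL

  patients <- data.frame(patient_id = ids,
                         label = unname(label),
                         split = unname(split_map[ids]),
                         n_notes = as.integer(table(masked$patient_id)[ids]),
                         stringsAsFactors = FALSE)
  structure(list(patients = patients, notes = masked, primary = primary,
                 ratio = ratio, seed = as.integer(seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort:", nrow(x$patients), "patients,", nrow(x$notes), "notes\n")
  print(table(split = x$patients$split, label = x$patients$label))
  invisible(x)
}
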