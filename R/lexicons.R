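#' SDOH topic lexicon
#'
#' Construct a topic lexicon: a named list mapping social-determinants-of-
#' health (SDOH) topic names to keyword sets. Keyword matching throughout the
#' package is case-insensitive and whole-word; multi-word keywords are matched
#' as contiguous phrases.
#'
#' @param topics named list of character vectors (topic name -> keywords).
#' @return object of class `topic_lexicon` (a validated named list).
#' @seealso [sdoh_topics()] for the default ten-topic lexicon,
#'   [read_topic_lexicon()] to load one from YAML/JSON.
#' @export
topic_lexicon <- function(topics) {
  if (!is.list(topics) || length(topics) == 0)
    stop("topics must be a non-empty named list")
  nms <- names(topics)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    stop("topic names must be unique and non-empty")
  for (t in nms) {
    kw <- topics[[t]]
    if (!is.character(kw) || length(kw) == 0 || any(!nzchar(kw)))
      stop("topic '", t, "' must have a non-empty character keyword set")
    topics[[t]] <- unique(kw)
  }
  structure(topics, class = "topic_lexicon")
}

#' Default SDOH topic lexicon (ten topics)
#'
#' The ten SDOH topic areas commonly discussed in clinical social work notes:
#' mental health, family, consultation/appointment, group session, risk of
#' death, clinician/hospital/medication, living condition/lifestyle/social
#' support, telephone encounter/online communication, abuse history, and
#' insurance/income. Keyword sets are compact seed lists adequate for
#' lexical-signal experiments; production analyses should supply their own
#' lexicon via [topic_lexicon()] or [read_topic_lexicon()].
#'
#' @return a `topic_lexicon` with ten topics.
#' @export
sdoh_topics <- function() {
  topic_lexicon(list(
    "Mental health" = c("anxiety", "depression", "distress", "coping",
                        "mood", "counseling"),
    "Family" = c("family", "daughter", "husband", "caregiver", "children"),
    "Consultation/Appointment" = c("consultation", "appointment", "referral",
                                   "scheduled"),
    "Group session" = c("group session", "support group", "workshop"),
    "Risk of death" = c("hospice", "end of life", "mortality", "palliative"),
    "Clinician/Hospital/Medication" = c("physician", "hospital", "nurse",
                                        "medication", "oncologist"),
    "Living condition/Lifestyle/Social support" = c("housing", "social support",
                                                    "lifestyle", "homeless",
                                                    "transportation", "living situation"),
    "Telephone encounter/Online communication" = c("telephone", "phone call",
                                                   "voicemail", "email"),
    "Abuse history" = c("abuse", "domestic violence", "trauma history"),
    "Insurance/Income" = c("insurance", "income", "financial", "medicaid",
                           "copay")
  ))
}

#' Drug lexicon for labeling and masking
#'
#' Two case-insensitive name sets: `targeted` (the targeted-therapy drugs that
#' define the positive TT-Yes label) and `maskable` (the superset of drug
#' names replaced by the token "drug" during masking). `targeted` must be a
#' subset of `maskable` so that label-defining names can never leak into
#' modeling text.
#'
#' @param targeted character vector of targeted-therapy drug names.
#' @param maskable character vector of all maskable drug names
#'   (default: `targeted` plus common non-targeted breast-cancer drugs).
#' @return object of class `drug_lexicon`, a list with elements
#'   `targeted` and `maskable`.
#' @export
drug_lexicon <- function(targeted = c("trastuzumab", "pertuzumab", "lapatinib",
                                      "neratinib", "palbociclib", "ribociclib",
                                      "abemaciclib", "everolimus", "olaparib",
                                      "alpelisib"),
                         maskable = union(targeted,
                                          c("tamoxifen", "letrozole",
                                            "anastrozole", "exemestane",
                                            "fulvestrant", "capecitabine",
                                            "paclitaxel", "doxorubicin",
                                            "cyclophosphamide", "carboplatin"))) {
  targeted <- unique(tolower(trimws(targeted)))
  maskable <- unique(tolower(trimws(maskable)))
  if (length(targeted) == 0 || any(!nzchar(targeted)))
    stop("targeted set must be non-empty with non-empty names")
  if (any(!nzchar(maskable))) stop("maskable names must be non-empty")
  if (!all(targeted %in% maskable))
    stop("targeted must be a subset of maskable")
  structure(list(targeted = targeted, maskable = maskable),
            class = "drug_lexicon")
}

#' Read a topic lexicon from YAML or JSON
#'
#' Expects a mapping of topic name to a list of keywords.
#'
#' @param path file path; format chosen by extension (.yaml/.yml or .json).
#' @return a `topic_lexicon`.
#' @export
read_topic_lexicon <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported lexicon format: .", ext)
  )
  topic_lexicon(lapply(raw, as.character))
}

#' Read a drug lexicon from plain-text name lists
#'
#' Each file holds one drug name per line; blank lines and lines starting
#' with `#` are ignored.
#'
#' @param targeted_path file of targeted-therapy names.
#' @param maskable_path optional file of all maskable names; if `NULL` the
#'   maskable set equals the targeted set.
#' @return a `drug_lexicon`.
#' @export
read_drug_lexicon <- function(targeted_path, maskable_path = NULL) {
  read_names <- function(p) {
    x <- trimws(readLines(p, warn = FALSE))
    x[nzchar(x) & !startsWith(x, "#")]
  }
  targeted <- read_names(targeted_path)
  maskable <- if (is.null(maskable_path)) targeted
              else union(targeted, read_names(maskable_path))
  drug_lexicon(targeted = targeted, maskable = maskable)
}

#' @export
print.topic_lexicon <- function(x, ...) {
  cat("SDOH topic lexicon:", length(x), "topics\n")
  for (t in names(x))
    cat(sprintf("  %-45s %d keywords\n", t, length(x[[t]])))
  invisible(x)
}

#' @export
print.drug_lexicon <- function(x, ...) {
  cat("Drug lexicon:", length(x$targeted), "targeted,",
      length(x$maskable), "maskable names\n")
  invisible(x)
}
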