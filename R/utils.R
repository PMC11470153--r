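# internal helpers shared across the package

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Coerce labels to binary (positive = targeted therapy administered)
#'
#' Accepts the label encodings used throughout the package: `"TT-Yes"` /
#' `"TT-No"` strings (or factors), logicals, and 0/1 numerics. The positive
#' class is the TT-Yes group.
#'
#' @param labels vector of labels.
#' @return integer vector of 0/1 with 1 = positive (TT-Yes).
#' @export
as_binary_label <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    ok <- labels %in% c("TT-Yes", "TT-No")
    if (!all(ok)) stop("unrecognized label value(s): ",
                       paste(unique(labels[!ok]), collapse = ", "))
    return(as.integer(labels == "TT-Yes"))
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  stop("unsupported label type")
}

# escape a literal string for use inside a perl regex; inner whitespace in
# multi-word names matches any whitespace run
regex_literal <- function(x) {
  esc <- gsub("([\\\\.^$|()\\[\\]{}*+?])", "\\\\\\1", x, perl = TRUE)
  gsub("\\s+", "\\\\s+", esc)
}

# one alternation pattern over names, longest (most tokens, then most chars)
# first so multi-word names win over their components; whole-word anchored
name_pattern <- function(names) {
  ntok <- lengths(strsplit(names, "\\s+"))
  ord <- order(-ntok, -nchar(names))
  alts <- paste(vapply(names[ord], regex_literal, ""), collapse = "|")
  paste0("(?<![[:alnum:]])(?:", alts, ")(?![[:alnum:]])")
}

#' Count whitespace-separated tokens
#'
#' @param text character vector.
#' @return integer vector of token counts (0 for empty strings).
#' @export
count_tokens <- function(text) {
  t <- trimws(text)
  n <- lengths(strsplit(t, "\\s+"))
  n[t == ""] <- 0L
  n
}
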