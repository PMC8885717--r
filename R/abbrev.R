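#' Abbreviation extraction
#'
#' Abbreviation/definition pairs are collected from two independent
#' detectors and merged with per-method provenance:
#' \itemize{
#'   \item the full-text bracket rule: every innermost parenthesized span
#'     with at least two non-digit characters is a candidate short form,
#'     whose definition is sought among the words adjacent to the brackets;
#'   \item the dedicated abbreviations section (IAO:0000606), split on the
#'     section's dominant delimiter.
#' }
#' One-sided entries (a short form with no definition) are never stored.
#'
#' @name abbrev
NULL

ABBREV_METHODS <- c("fulltext_bracket", "abbreviations_section")

# Word-level tokenization preserving original text.
tokenize_words <- function(text) {
  strsplit(trimws(text), "[[:space:]]+")[[1]]
}

# Can `chars` (after the first) be found, in order and case-insensitively,
# in the concatenation of `words` starting from the character after the
# first char of words[1]? Hyphens inside words are transparent. Returns the
# index of the last word consumed, or NA.
match_chars_forward <- function(chars, words) {
  if (length(words) == 0L) return(NA_integer_)
  if (tolower(substr(words[1], 1, 1)) != tolower(chars[1]))
    return(NA_integer_)
  need <- tolower(chars[-1])
  w <- 1L; pos <- 2L  # next char to inspect in words[w]
  last_used <- 1L
  for (ch in need) {
    repeat {
      if (w > length(words)) return(NA_integer_)
      cs <- strsplit(tolower(words[w]), "")[[1]]
      found <- FALSE
      while (pos <= length(cs)) {
        if (cs[pos] == ch) { found <- TRUE; pos <- pos + 1L; break }
        pos <- pos + 1L
      }
      if (found) { last_used <- w; break }
      w <- w + 1L; pos <- 1L
    }
  }
  last_used
}

#' Extract abbreviation pairs from plain passage text
#'
#' Implements the bracket rule: for each innermost parenthesized span with
#' two or more non-digit characters, words adjacent to the brackets are
#' scanned for a definition — a run of words whose first word starts
#' (case-insensitively) with the first bracket character and whose
#' following words contain the remaining bracket characters in order
#' (hyphens transparent). The window is min(|short| + 5, 2 |short|) words
#' per side; the left side is tried first, nearest start first, so the
#' shortest valid definition wins; at most one definition per bracket
#' occurrence.
#'
#' @param text Markup-free passage text.
#' @return data.frame with columns `short`, `long` (zero rows if none).
#' @examples
#' extract_inline("genome-wide association study (GWAS) data")
#' @export
extract_inline <- function(text) {
  out <- data.frame(short = character(0), long = character(0),
                    stringsAsFactors = FALSE)
  if (is.null(text) || !nzchar(text)) return(out)
  m <- gregexpr("\\(([^()]*)\\)", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(out)
  lens <- attr(m, "match.length")
  for (k in seq_along(m)) {
    inside <- substr(text, m[k] + 1L, m[k] + lens[k] - 2L)
    sf <- trimws(inside)
    sf_chars <- strsplit(sf, "")[[1]]
    sf_core <- sf_chars[grepl("[^[:space:]]", sf_chars)]
    non_digit <- sum(!grepl("[0-9]", sf_core))
    if (non_digit < 2L) next
    letters_only <- sf_core[grepl("[[:alnum:]]", sf_core)]
    if (length(letters_only) < 2L) next
    window <- min(length(letters_only) + 5L, 2L * length(letters_only))

    left_txt <- substr(text, 1L, m[k] - 1L)
    right_txt <- substr(text, m[k] + lens[k], nchar(text))
    left_words <- tokenize_words(left_txt)
    right_words <- tokenize_words(gsub("^[[:punct:]]+", "", right_txt))

    long <- NA_character_
    # left of the bracket, nearest start first (shortest definition)
    lw <- tail(left_words, window)
    if (length(lw)) {
      for (s in rev(seq_along(lw))) {
        hit <- match_chars_forward(letters_only, lw[s:length(lw)])
        if (!is.na(hit)) {
          long <- paste(lw[s:length(lw)], collapse = " ")
          break
        }
      }
    }
    if (is.na(long)) {
      rw <- head(right_words, window)
      if (length(rw)) {
        for (s in seq_along(rw)) {
          hit <- match_chars_forward(letters_only, rw[s:length(rw)])
          if (!is.na(hit)) {
            long <- paste(rw[s:(s + hit - 1L)], collapse = " ")
            break
          }
        }
      }
    }
    if (!is.na(long)) {
      long <- gsub("[[:punct:]]+$", "", long)
      out <- rbind(out, data.frame(short = sf, long = long,
                                   stringsAsFactors = FALSE))
    }
  }
  unique(out)
}

#' Parse a dedicated abbreviations section into pairs
#'
#' The section's dominant delimiter convention is detected by trying each
#' (item separator, pair delimiter) combination from semicolon/newline/
#' comma crossed with colon/equals/comma/dash and keeping the one that
#' yields the most two-sided pairs. Entries lacking either side are
#' dropped.
#'
#' @param passages Character vector of abbreviation-section passage texts.
#' @return data.frame with columns `short`, `long`.
#' @examples
#' parse_abbrev_section("RP: reverse phase; TOF: time of flight")
#' @export
parse_abbrev_section <- function(passages) {
  text <- paste(passages, collapse = "\n")
  out <- data.frame(short = character(0), long = character(0),
                    stringsAsFactors = FALSE)
  if (!nzchar(trimws(text))) return(out)
  seps <- c(";", "\n", ",")
  delims <- c(":", "=", ",", ";")
  best <- out
  for (sep in seps) for (delim in delims) {
    if (sep == delim) next
    items <- strsplit(text, sep, fixed = TRUE)[[1]]
    pairs <- lapply(items, function(it) {
      if (!grepl(delim, it, fixed = TRUE)) return(NULL)
      at <- regexpr(delim, it, fixed = TRUE)
      s <- trimws(substr(it, 1L, at - 1L))
      l <- trimws(substr(it, at + nchar(delim), nchar(it)))
      if (!nzchar(s) || !nzchar(l)) return(NULL)
      data.frame(short = s, long = l, stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, TRUE)])
    if (!is.null(pairs) && nrow(pairs) > nrow(best)) best <- pairs
  }
  if (nrow(best) == 0L)
    pc_warn("abbreviations section has no recognizable delimiter",
            class = "pubcorpus_abbrev_nodelim")
  unique(best)
}

#' Merge inline and section abbreviation pairs into an AbbreviationSet
#'
#' Identical (short, long) pairs union their detection methods; the same
#' short form with different long forms keeps each long form as a distinct
#' entry with its own methods. Commutative and idempotent.
#'
#' @param inline_pairs data.frame (`short`, `long`) from [extract_inline()].
#' @param section_pairs data.frame (`short`, `long`) from
#'   [parse_abbrev_section()].
#' @return A `pubcorpus_abbrevset`: named list short form -> named list
#'   long form -> character vector of methods.
#' @export
merge_abbreviations <- function(inline_pairs = NULL, section_pairs = NULL) {
  set <- list()
  add <- function(set, pairs, method) {
    if (is.null(pairs) || nrow(pairs) == 0L) return(set)
    for (i in seq_len(nrow(pairs))) {
      s <- pairs$short[i]; l <- pairs$long[i]
      if (!nzchar(s) || !nzchar(l)) next
      methods <- set[[s]][[l]] %||% character(0)
      set[[s]][[l]] <- sort(unique(c(methods, method)))
    }
    set
  }
  set <- add(set, inline_pairs, "fulltext_bracket")
  set <- add(set, section_pairs, "abbreviations_section")
  if (length(set)) set <- set[order(names(set))]
  structure(set, class = "pubcorpus_abbrevset")
}

#' Write an AbbreviationSet to JSON
#' @param abbrevs A `pubcorpus_abbrevset`.
#' @param path Destination (conventional suffix `_abbreviations.json`).
#' @param doc_id Article identifier.
#' @param source,date Collection-level provenance strings.
#' @return `path`, invisibly.
#' @export
write_abbreviations <- function(abbrevs, path, doc_id = "doc",
                                source = "pubcorpus",
                                date = format(Sys.Date(), "%Y%m%d")) {
  obj <- list(source = source, date = date,
              key = "pubcorpus_abbreviations.key",
              documents = list(list(id = doc_id,
                                    abbreviations = unclass(abbrevs))))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read an abbreviations JSON file
#' @param path Path to a `*_abbreviations.json` file.
#' @return `list(doc_id, abbreviations)` where `abbreviations` is a
#'   `pubcorpus_abbrevset`.
#' @export
read_abbreviations <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc <- x$documents[[1]]
  set <- lapply(doc$abbreviations, function(longs)
    lapply(longs, function(methods) unlist(methods)))
  list(doc_id = doc$id,
       abbreviations = structure(set, class = "pubcorpus_abbrevset"))
}

#' Structurally validate an abbreviations JSON file or object
#' @param x Path or parsed object.
#' @return `TRUE` invisibly.
#' @export
validate_abbrev_json <- function(x) {
  if (is.character(x)) x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  for (f in c("source", "date", "key", "documents"))
    if (is.null(x[[f]])) pc_stop("abbreviations JSON missing field '", f,
                                 "'", class = "pubcorpus_schema_error")
  for (d in x$documents) {
    for (s in names(d$abbreviations)) {
      longs <- d$abbreviations[[s]]
      if (length(longs) == 0L)
        pc_stop("abbreviation '", s, "' has no long form",
                class = "pubcorpus_schema_error")
      for (l in names(longs)) {
        methods <- unlist(longs[[l]])
        if (length(methods) == 0L || anyDuplicated(methods) ||
            !all(methods %in% ABBREV_METHODS))
          pc_stop("abbreviation '", s, "' has invalid method list",
                  class = "pubcorpus_schema_error")
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.pubcorpus_abbrevset <- function(x, ...) {
  cat("<pubcorpus_abbrevset>", length(x), "short forms\n")
  invisible(x)
}
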