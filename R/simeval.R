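#' Output comparison by longest-common-subsequence similarity
#'
#' Two pipeline outputs are compared unit by unit (paragraph passages for
#' BioC collections, cells for table JSON) with the longest common
#' subsequence (LCS):
#' \itemize{
#'   \item unidirectional similarity — |LCS(reference, candidate)| /
#'     |reference| — measures how much of the reference is retained, in
#'     order, by the candidate (non-symmetric by design: a candidate may
#'     legitimately contain extra content such as link anchor text);
#'   \item bidirectional similarity takes the maximum of both directions.
#' }
#' Units above 20,000 characters fall back to a banded LCS approximation
#' and are flagged, never silently. An empty reference scores 1.0 by
#' convention so missing optional fields do not poison medians.
#'
#' @name simeval
NULL

LONG_UNIT_LIMIT <- 20000L
BAND_WIDTH <- 2000L

#' Unidirectional LCS similarity
#' @param reference Reference string.
#' @param candidate Candidate string.
#' @return Ratio in [0, 1]: |LCS|/|reference|; 1.0 when the reference is
#'   empty. The result carries attribute `approximate = TRUE` when the
#'   banded fallback was used.
#' @examples
#' lcs_similarity("abcd", "axbycz")  # 0.75
#' @export
lcs_similarity <- function(reference, candidate) {
  a <- utf8ToInt(enc2utf8(reference))
  b <- utf8ToInt(enc2utf8(candidate))
  if (length(a) == 0L) return(1)
  if (length(b) == 0L) return(0)
  if (length(a) > LONG_UNIT_LIMIT || length(b) > LONG_UNIT_LIMIT) {
    pc_warn("unit longer than ", LONG_UNIT_LIMIT,
            " characters: banded LCS approximation used",
            class = "pubcorpus_banded_lcs")
    val <- lcs_length_banded_int(a, b, BAND_WIDTH) / length(a)
    return(structure(val, approximate = TRUE))
  }
  lcs_length_int(a, b) / length(a)
}

#' Bidirectional LCS similarity
#' @param a,b Strings to compare.
#' @return `max(lcs_similarity(a, b), lcs_similarity(b, a))`; symmetric.
#' @export
bidirectional_similarity <- function(a, b) {
  max(lcs_similarity(a, b), lcs_similarity(b, a))
}

# Characters of the reference not matched by one maximal LCS against the
# candidate, as runs: data.frame(start, end, text) in reference coordinates.
diff_spans <- function(reference, candidate) {
  a <- utf8ToInt(enc2utf8(reference))
  b <- utf8ToInt(enc2utf8(candidate))
  empty <- data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE)
  if (length(a) == 0L) return(empty)
  if (as.double(length(a)) * length(b) > 2.5e7) {
    # too large for full backtrack; report a single unresolved span
    return(data.frame(start = 1L, end = length(a),
                      text = NA_character_, stringsAsFactors = FALSE))
  }
  matched <- lcs_match_ref_int(a, b)
  un <- setdiff(seq_along(a), matched)
  if (length(un) == 0L) return(empty)
  runs <- split(un, cumsum(c(TRUE, diff(un) != 1L)))
  do.call(rbind, lapply(runs, function(ix)
    data.frame(start = ix[1], end = ix[length(ix)],
               text = intToUtf8(a[ix]), stringsAsFactors = FALSE)))
}

# Flatten a BioC collection into comparison units.
bioc_units <- function(x) {
  if (is.character(x)) x <- read_bioc(x)
  units <- list()
  for (d in x$documents)
    for (i in seq_along(d$passages))
      units[[length(units) + 1L]] <-
        list(id = paste0(d$id, "/passage_", i), text = d$passages[[i]]$text)
  units
}

# Flatten table JSON into per-cell units keyed by table identifier.
table_units <- function(x) {
  if (is.character(x)) x <- read_table_json(x)
  units <- list()
  for (t in x$tables) {
    for (i in seq_len(nrow(t$column_headers)))
      units[[length(units) + 1L]] <-
        list(id = t$column_headers$cell_id[i],
             text = as.character(t$column_headers$text[i]))
    for (s in t$sections) for (row in s$rows) for (cell in row)
      units[[length(units) + 1L]] <-
        list(id = cell$cell_id, text = as.character(cell$value))
  }
  units
}

#' Compare two pipeline outputs unit by unit
#'
#' Units (passages or cells) are paired by order within matching document /
#' table identifiers; each pair is scored with [lcs_similarity()] (first
#' argument as reference) and the differing reference characters are
#' extracted. The aggregate is the median and interquartile range of the
#' unit similarities.
#'
#' @param reference,candidate File paths or parsed objects: BioC
#'   collections for `granularity = "paragraph"`, table JSON for
#'   `granularity = "cell"`.
#' @param granularity `"paragraph"` or `"cell"`.
#' @return A `pubcorpus_simreport`: `units` data.frame (`ref_id`,
#'   `cand_id`, `similarity`, `n_diff_chars`, `diff_text`), `diffs` (list
#'   of span tables), and `aggregate` (median, q1, q3, n).
#' @export
compare_outputs <- function(reference, candidate,
                            granularity = c("paragraph", "cell")) {
  granularity <- match.arg(granularity)
  ru <- if (granularity == "paragraph") bioc_units(reference)
        else table_units(reference)
  cu <- if (granularity == "paragraph") bioc_units(candidate)
        else table_units(candidate)
  if (length(ru) != length(cu)) {
    k <- min(length(ru), length(cu)) + 1L
    bad <- if (length(ru) > length(cu)) ru[[k]]$id else cu[[k]]$id
    pc_stop("outputs are not unit-pairable: no counterpart for unit '",
            bad, "' (", length(ru), " vs ", length(cu), " units)",
            class = "pubcorpus_pairing_error")
  }
  n <- length(ru)
  sim <- numeric(n); ndiff <- integer(n); dtext <- character(n)
  diffs <- vector("list", n)
  for (i in seq_len(n)) {
    sim[i] <- as.numeric(lcs_similarity(ru[[i]]$text, cu[[i]]$text))
    sp <- diff_spans(ru[[i]]$text, cu[[i]]$text)
    diffs[[i]] <- sp
    ndiff[i] <- if (nrow(sp)) sum(sp$end - sp$start + 1L) else 0L
    dtext[i] <- paste(sp$text, collapse = "")
  }
  units <- data.frame(
    ref_id = vapply(ru, `[[`, "", "id"),
    cand_id = vapply(cu, `[[`, "", "id"),
    similarity = sim, n_diff_chars = ndiff, diff_text = dtext,
    stringsAsFactors = FALSE)
  agg <- list(median = stats::median(sim),
              q1 = unname(stats::quantile(sim, 0.25)),
              q3 = unname(stats::quantile(sim, 0.75)), n = n)
  structure(list(units = units, diffs = diffs, aggregate = agg,
                 granularity = granularity),
            class = "pubcorpus_simreport")
}

#' @export
print.pubcorpus_simreport <- function(x, ...) {
  cat("<pubcorpus_simreport>", x$aggregate$n, x$granularity,
      sprintf("units; median %.4f (IQR %.4f-%.4f)\n", x$aggregate$median,
              x$aggregate$q1, x$aggregate$q3))
  invisible(x)
}

#' Write a similarity report as JSON plus a side-by-side diff text file
#' @param report A `pubcorpus_simreport`.
#' @param json_path Destination for the JSON report.
#' @param diff_path Optional destination for a human-readable diff listing
#'   of all units below similarity 1.
#' @return `json_path`, invisibly.
#' @export
write_sim_report <- function(report, json_path, diff_path = NULL) {
  obj <- list(granularity = report$granularity,
              aggregate = report$aggregate,
              units = report$units)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  if (!is.null(diff_path)) {
    lines <- character(0)
    for (i in seq_len(nrow(report$units))) {
      u <- report$units[i, ]
      if (u$similarity >= 1) next
      lines <- c(lines,
                 sprintf("unit %s | %s  similarity=%.4f", u$ref_id,
                         u$cand_id, u$similarity),
                 sprintf("  differing reference characters: %s",
                         u$diff_text),
                 "")
    }
    if (length(lines) == 0L) lines <- "all units identical"
    writeLines(lines, diff_path, useBytes = TRUE)
  }
  invisible(json_path)
}
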