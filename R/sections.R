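#' Section classification with IAO document-part terms
#'
#' Publication section headers are heterogeneous ("Methods", "Experimental
#' procedures", "Methodology", ...). Every header is mapped to terms from
#' the Information Artifact Ontology (IAO) document-part branch by a cascade
#' of three strategies:
#' \enumerate{
#'   \item lexical matching after LOOM-style normalization (lowercase,
#'     all non-alphanumeric characters removed);
#'   \item fuzzy matching at a similarity threshold of 0.8, where the score
#'     between normalized strings a, b is 2*LCS(a,b)/(|a|+|b|);
#'   \item prediction from a weighted directed graph of section-header
#'     sequences, anchored on the headers of the document that could be
#'     mapped.
#' }
#' For the digraph, each document contributes a directed path graph (DPG):
#' the linear chain of its main headers in reading order with consecutive
#' duplicates collapsed — no cycles, no self-edges. Merging many DPGs gives
#' a digraph whose node and edge weights count the number of documents in
#' which each header and transition occur.
#'
#' @name sections
NULL

START_NODE <- "#document-start"

#' LOOM-style header normalization
#'
#' Lowercases and removes every non-alphanumeric character. Idempotent.
#' @param text Header string(s).
#' @return Normalized string(s).
#' @examples
#' normalize_header("Materials and Methods")  # "materialsandmethods"
#' @export
normalize_header <- function(text) {
  gsub("[^[:alnum:]]+", "", tolower(text))
}

#' Load the packaged (or a user-supplied) IAO document-part lexicon
#'
#' The lexicon is a TSV with columns `iao_id`, `label`, `synonym`, one row
#' per synonym (the preferred label is itself listed as a synonym). The
#' packaged file pins IAO v2020-06-10 plus the synonym and term additions
#' identified from section-header analysis; proposed terms without published
#' IAO ids carry provisional `AUTO:` ids. To refresh against a newer IAO
#' release, regenerate the TSV from the ontology's document-part branch and
#' pass its path here.
#'
#' @param path TSV path; default is the packaged lexicon.
#' @return A `pubcorpus_lexicon`: entry table, normalized-synonym lookup,
#'   and version tag.
#' @export
load_lexicon <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "iao_lexicon.tsv", package = "pubcorpus")
  tab <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("iao_id", "label", "synonym") %in% names(tab)))
  tab$norm <- normalize_header(tab$synonym)
  tab <- tab[nzchar(tab$norm), ]
  dup <- tapply(tab$iao_id, tab$norm, function(ids) length(unique(ids)) > 1L)
  if (any(dup))
    pc_stop("lexicon synonym(s) map to multiple entries: ",
            paste(names(dup)[dup], collapse = ", "),
            class = "pubcorpus_lexicon_error")
  entries <- unique(tab[, c("iao_id", "label")])
  if (anyDuplicated(entries$iao_id))
    pc_stop("duplicate iao_id with conflicting labels in lexicon",
            class = "pubcorpus_lexicon_error")
  lookup <- setNames(tab$iao_id, tab$norm)
  lookup <- lookup[!duplicated(names(lookup))]
  structure(list(entries = entries, synonyms = tab, lookup = lookup,
                 version = "IAO v2020-06-10 + header-analysis additions"),
            class = "pubcorpus_lexicon")
}

iao_label <- function(lexicon, iao_id) {
  lexicon$entries$label[match(iao_id, lexicon$entries$iao_id)]
}

#' Exact lexical match of a header against the lexicon
#' @param header Header string.
#' @param lexicon A `pubcorpus_lexicon`.
#' @return The matching `iao_id`, or `NA_character_` if none.
#' @examples
#' lex <- load_lexicon()
#' match_lexical("Materials and Methods", lex)  # "IAO:0000317"
#' @export
match_lexical <- function(header, lexicon) {
  id <- unname(lexicon$lookup[normalize_header(header)])
  if (is.null(id) || is.na(id)) NA_character_ else id
}

#' Fuzzy-match configuration
#' @param threshold Similarity threshold in (0, 1]; default 0.8.
#' @return A `pubcorpus_fuzzy_cfg`.
#' @export
fuzzy_config <- function(threshold = 0.8) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  structure(list(threshold = threshold), class = "pubcorpus_fuzzy_cfg")
}

# 2*LCS/(|a|+|b|) similarity on raw strings (code points).
lcs_ratio <- function(a, b) {
  ai <- utf8ToInt(enc2utf8(a)); bi <- utf8ToInt(enc2utf8(b))
  if (length(ai) + length(bi) == 0L) return(1)
  2 * lcs_length_int(ai, bi) / (length(ai) + length(bi))
}

#' Fuzzy match of a header against the lexicon
#'
#' Scores the normalized header against every entry's normalized labels and
#' synonyms with the ratio 2*LCS(a,b)/(|a|+|b|), keeping each entry's best
#' synonym score. Entries at or above the threshold are returned sorted by
#' descending score.
#'
#' @param header Header string (normally one that failed [match_lexical()]).
#' @param lexicon A `pubcorpus_lexicon`.
#' @param cfg A [fuzzy_config()].
#' @return data.frame with columns `iao_id`, `iao_name`, `score` (possibly
#'   zero rows).
#' @examples
#' lex <- load_lexicon()
#' match_fuzzy("experemintal section", lex)  # methods section, score ~0.895
#' @export
match_fuzzy <- function(header, lexicon, cfg = fuzzy_config()) {
  h <- normalize_header(header)
  syn <- lexicon$synonyms
  scores <- vapply(syn$norm, function(s) lcs_ratio(h, s), 0)
  best <- tapply(scores, syn$iao_id, max)
  keep <- best[best >= cfg$threshold]
  ids <- names(keep)[order(-keep, names(keep))]
  data.frame(iao_id = ids, iao_name = iao_label(lexicon, ids),
             score = as.numeric(keep[ids]), stringsAsFactors = FALSE)
}

# Resolve one header through the lexical -> fuzzy cascade.
# Returns data.frame(iao_id, iao_name, method); zero rows if unresolved.
resolve_header <- function(header, lexicon, cfg = fuzzy_config()) {
  id <- match_lexical(header, lexicon)
  if (!is.na(id))
    return(data.frame(iao_id = id, iao_name = iao_label(lexicon, id),
                      method = "lexical", stringsAsFactors = FALSE))
  fz <- match_fuzzy(header, lexicon, cfg)
  if (nrow(fz)) {
    top <- fz[fz$score == fz$score[1L], , drop = FALSE]
    return(data.frame(iao_id = top$iao_id, iao_name = top$iao_name,
                      method = "fuzzy", stringsAsFactors = FALSE))
  }
  data.frame(iao_id = character(0), iao_name = character(0),
             method = character(0), stringsAsFactors = FALSE)
}

#' Build the directed path graph (DPG) of a document's main headers
#'
#' Consecutive duplicate headers (same normalized form) are collapsed into a
#' single node; the result is a linear chain with no cycles and no
#' self-edges. Each node is tagged with the outcome of the lexical/fuzzy
#' cascade, or left unmapped.
#'
#' @param headers Main headers in document order.
#' @param lexicon A `pubcorpus_lexicon`.
#' @param cfg A [fuzzy_config()].
#' @return A `pubcorpus_dpg`: list of nodes `list(header, norm, terms,
#'   status)` where `status` is "lexical", "fuzzy" or "unmapped".
#' @export
build_dpg <- function(headers, lexicon, cfg = fuzzy_config()) {
  nodes <- list()
  prev_norm <- NULL
  for (h in headers) {
    nh <- normalize_header(h)
    if (!is.null(prev_norm) && identical(nh, prev_norm)) next
    res <- resolve_header(h, lexicon, cfg)
    nodes[[length(nodes) + 1L]] <- list(
      header = h, norm = nh,
      terms = res[, c("iao_id", "iao_name")],
      status = if (nrow(res)) res$method[1L] else "unmapped")
    prev_norm <- nh
  }
  structure(list(nodes = nodes), class = "pubcorpus_dpg")
}

#' @export
print.pubcorpus_dpg <- function(x, ...) {
  cat("<pubcorpus_dpg>", length(x$nodes), "nodes\n")
  for (n in x$nodes)
    cat("  ", n$header, " [", n$status, "] ",
        paste(n$terms$iao_id, collapse = ","), "\n", sep = "")
  invisible(x)
}

# Digraph node key for a DPG node: mapped nodes live under their IAO
# preferred label, unmapped nodes under their normalized header text.
dpg_node_key <- function(node) {
  if (node$status == "unmapped" || nrow(node$terms) == 0L) node$norm
  else node$terms$iao_name[1L]
}

#' Create an empty section digraph
#' @return A `pubcorpus_digraph` with no nodes or edges.
#' @export
empty_digraph <- function() {
  structure(list(
    nodes = data.frame(label = character(0), weight = integer(0),
                       stringsAsFactors = FALSE),
    edges = data.frame(from = character(0), to = character(0),
                       weight = integer(0), stringsAsFactors = FALSE)),
    class = "pubcorpus_digraph")
}

#' Merge one document's DPG into the section digraph
#'
#' Every traversed node and edge has its weight incremented by exactly 1
#' (created at weight 1 if absent), so weights count publications. A
#' synthetic document-start node precedes every chain, giving leading
#' unmapped headers a left anchor.
#'
#' @param digraph A `pubcorpus_digraph`.
#' @param dpg A `pubcorpus_dpg`.
#' @return The updated digraph.
#' @export
accumulate_digraph <- function(digraph, dpg) {
  stopifnot(inherits(digraph, "pubcorpus_digraph"),
            inherits(dpg, "pubcorpus_dpg"))
  if (length(dpg$nodes) == 0L) return(digraph)
  keys <- c(START_NODE, vapply(dpg$nodes, dpg_node_key, ""))
  for (k in keys) {
    i <- match(k, digraph$nodes$label)
    if (is.na(i))
      digraph$nodes <- rbind(digraph$nodes,
                             data.frame(label = k, weight = 1L,
                                        stringsAsFactors = FALSE))
    else digraph$nodes$weight[i] <- digraph$nodes$weight[i] + 1L
  }
  if (length(keys) > 1L) {
    for (i in seq_len(length(keys) - 1L)) {
      f <- keys[i]; t <- keys[i + 1L]
      j <- which(digraph$edges$from == f & digraph$edges$to == t)
      if (length(j))
        digraph$edges$weight[j] <- digraph$edges$weight[j] + 1L
      else
        digraph$edges <- rbind(digraph$edges,
                               data.frame(from = f, to = t, weight = 1L,
                                          stringsAsFactors = FALSE))
    }
  }
  digraph
}

#' @export
print.pubcorpus_digraph <- function(x, ...) {
  cat("<pubcorpus_digraph>", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

#' Save / load a section digraph as a JSON adjacency list
#' @param digraph A `pubcorpus_digraph`.
#' @param path JSON file path.
#' @return `path` invisibly ([write_digraph()]); the digraph
#'   ([read_digraph()]). The round trip is exact.
#' @export
write_digraph <- function(digraph, path) {
  obj <- list(
    nodes = lapply(seq_len(nrow(digraph$nodes)), function(i)
      list(label = digraph$nodes$label[i],
           weight = digraph$nodes$weight[i])),
    edges = lapply(seq_len(nrow(digraph$edges)), function(i)
      list(from = digraph$edges$from[i], to = digraph$edges$to[i],
           weight = digraph$edges$weight[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_digraph
#' @export
read_digraph <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  g <- empty_digraph()
  if (length(x$nodes))
    g$nodes <- data.frame(
      label = vapply(x$nodes, `[[`, "", "label"),
      weight = vapply(x$nodes, function(n) as.integer(n$weight), 0L),
      stringsAsFactors = FALSE)
  if (length(x$edges))
    g$edges <- data.frame(
      from = vapply(x$edges, `[[`, "", "from"),
      to = vapply(x$edges, `[[`, "", "to"),
      weight = vapply(x$edges, function(e) as.integer(e$weight), 0L),
      stringsAsFactors = FALSE)
  g
}

# Enumerate directed paths from `from` with exactly k interior nodes, ending
# at `to` (or anywhere when `to` is NA), interior nodes restricted to
# IAO-labelled digraph nodes. Returns list of list(interior, score).
enumerate_paths <- function(digraph, from, to, k, iao_labels,
                            max_paths = 10000L) {
  out <- list()
  adj <- split(seq_len(nrow(digraph$edges)), digraph$edges$from)
  dfs <- function(node, interior, score) {
    if (length(out) >= max_paths) return()
    if (length(interior) == k) {
      if (is.na(to)) {
        out[[length(out) + 1L]] <<- list(interior = interior, score = score)
      } else {
        j <- which(digraph$edges$from == node & digraph$edges$to == to)
        if (length(j))
          out[[length(out) + 1L]] <<-
            list(interior = interior, score = score + digraph$edges$weight[j])
      }
      return()
    }
    for (e in adj[[node]] %||% integer(0)) {
      nxt <- digraph$edges$to[e]
      if (!nxt %in% iao_labels) next
      if (nxt %in% interior || identical(nxt, from)) next  # simple paths only
      dfs(nxt, c(interior, nxt), score + digraph$edges$weight[e])
    }
  }
  dfs(from, character(0), 0)
  out
}

#' Predict IAO terms for unmapped DPG nodes from the section digraph
#'
#' For each maximal run of consecutive unmapped headers, let A be the
#' nearest preceding mapped anchor (the synthetic document-start node if
#' none) and B the nearest following mapped anchor (or none at document
#' end). Candidate assignments are the interior nodes of directed paths
#' A -> ... -> B in the digraph whose interior length equals the run length,
#' with interior nodes restricted to IAO-labelled digraph nodes. Paths are
#' scored by the sum of their edge weights; the best path's terms are
#' assigned positionally, and ties retain all tied terms (a header may end
#' up mapped to multiple IAO terms).
#'
#' @param dpg A `pubcorpus_dpg`.
#' @param digraph A trained `pubcorpus_digraph`.
#' @param lexicon A `pubcorpus_lexicon` (to translate labels back to ids).
#' @return The DPG with predicted nodes tagged `status = "digraph"`. If the
#'   DPG has no mapped nodes at all, it is returned unchanged with a
#'   warning.
#' @export
predict_unmapped <- function(dpg, digraph, lexicon) {
  stopifnot(inherits(dpg, "pubcorpus_dpg"),
            inherits(digraph, "pubcorpus_digraph"))
  status <- vapply(dpg$nodes, `[[`, "", "status")
  if (!length(status) || all(status == "unmapped")) {
    if (length(status))
      pc_warn("no anchor headers could be mapped; digraph prediction ",
              "skipped", class = "pubcorpus_no_anchor")
    return(dpg)
  }
  if (!any(status == "unmapped")) return(dpg)
  iao_labels <- lexicon$entries$label

  i <- 1L
  n <- length(status)
  while (i <= n) {
    if (status[i] != "unmapped") { i <- i + 1L; next }
    j <- i
    while (j < n && status[j + 1L] == "unmapped") j <- j + 1L
    run <- i:j
    a_key <- if (i == 1L) START_NODE else dpg_node_key(dpg$nodes[[i - 1L]])
    b_key <- if (j == n) NA_character_ else dpg_node_key(dpg$nodes[[j + 1L]])
    paths <- enumerate_paths(digraph, a_key, b_key, length(run), iao_labels)
    if (length(paths)) {
      scores <- vapply(paths, `[[`, 0, "score")
      best <- paths[scores == max(scores)]
      for (pos in seq_along(run)) {
        labels <- sort(unique(vapply(best, function(p) p$interior[pos], "")))
        ids <- lexicon$entries$iao_id[match(labels, lexicon$entries$label)]
        dpg$nodes[[run[pos]]]$terms <-
          data.frame(iao_id = ids, iao_name = labels, stringsAsFactors = FALSE)
        dpg$nodes[[run[pos]]]$status <- "digraph"
      }
    }
    i <- j + 1L
  }
  dpg
}

#' Classify every passage of an article with IAO terms
#'
#' Applies the full cascade. Main headers (depth 1 of each passage's heading
#' path) are resolved lexically, then fuzzily, then — for headers still
#' unmapped — by digraph prediction anchored on the mapped headers of the
#' same document. A sub-header is first classified on its own (lexical,
#' fuzzy); only if unresolvable does it inherit its main header's terms.
#'
#' @param model A `pubcorpus_article`.
#' @param lexicon A `pubcorpus_lexicon`.
#' @param digraph Optional trained `pubcorpus_digraph` (NULL disables
#'   digraph prediction).
#' @param cfg A [fuzzy_config()].
#' @return A list, aligned with `model$passages`, of data.frames with
#'   columns `iao_name`, `iao_id` (zero rows means unclassifiable, which
#'   triggers a warning).
#' @export
classify_sections <- function(model, lexicon, digraph = NULL,
                              cfg = fuzzy_config()) {
  stopifnot(inherits(model, "pubcorpus_article"))
  mains <- vapply(model$passages, function(p)
    if (length(p$heading_path)) p$heading_path[1L] else NA_character_, "")
  main_seq <- mains[!is.na(mains)]
  main_seq <- main_seq[c(TRUE, normalize_header(main_seq[-1]) !=
                           normalize_header(main_seq[-length(main_seq)]))]
  dpg <- build_dpg(main_seq, lexicon, cfg)
  if (!is.null(digraph) &&
      any(vapply(dpg$nodes, `[[`, "", "status") == "unmapped"))
    dpg <- withCallingHandlers(
      predict_unmapped(dpg, digraph, lexicon),
      pubcorpus_no_anchor = function(w) invokeRestart("muffleWarning"))
  main_terms <- setNames(
    lapply(dpg$nodes, function(n) n$terms),
    vapply(dpg$nodes, `[[`, "", "norm"))

  unresolved <- FALSE
  out <- lapply(model$passages, function(p) {
    hp <- p$heading_path
    if (!length(hp)) {
      unresolved <<- TRUE
      return(data.frame(iao_name = character(0), iao_id = character(0),
                        stringsAsFactors = FALSE))
    }
    # deepest heading that resolves on its own wins
    if (length(hp) > 1L) {
      for (d in rev(seq_along(hp))[-length(hp)]) {
        res <- resolve_header(hp[d], lexicon, cfg)
        if (nrow(res))
          return(data.frame(iao_name = res$iao_name, iao_id = res$iao_id,
                            stringsAsFactors = FALSE))
      }
    }
    terms <- main_terms[[normalize_header(hp[1L])]]
    if (is.null(terms) || nrow(terms) == 0L) {
      unresolved <<- TRUE
      return(data.frame(iao_name = character(0), iao_id = character(0),
                        stringsAsFactors = FALSE))
    }
    data.frame(iao_name = terms$iao_name, iao_id = terms$iao_id,
               stringsAsFactors = FALSE)
  })
  if (unresolved)
    pc_warn("one or more passages could not be classified with IAO terms",
            class = "pubcorpus_unclassified")
  out
}
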