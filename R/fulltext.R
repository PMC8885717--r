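#' Full-text HTML to BioC
#'
#' Parses a publication's full-text HTML into an ordered model of passages,
#' each carrying the heading path (section title, subtitle, ...) that governs
#' it, then emits a BioC JSON collection in which every passage is annotated
#' with IAO document-part terms. All markup, including text formatting such
#' as emphasis, superscript and subscript, is removed from publication text;
#' link anchor text is retained. Table content is routed to the tables module
#' and any passage classified as the abbreviations section (IAO:0000606) is
#' routed to the abbreviations module, so neither appears in the BioC output.
#'
#' @name fulltext
NULL

#' Strip HTML markup from a text fragment
#'
#' Removes every tag, keeps anchor (link) inner text, decodes entity
#' references to UTF-8 characters, collapses whitespace runs to single
#' spaces and trims. Total and idempotent.
#'
#' @param fragment A markup (or plain-text) string.
#' @return The plain-text string.
#' @examples
#' strip_markup("see <a href='#f1'>Figure 1</a>")
#' strip_markup("10<sup>3</sup> samples")
#' @export
strip_markup <- function(fragment) {
  if (is.null(fragment) || is.na(fragment) || !nzchar(fragment)) return("")
  doc <- xml2::read_html(paste0("<div id='pc-root'>", enc2utf8(fragment),
                                "</div>"))
  node <- xml2::xml_find_first(doc, "//div[@id='pc-root']")
  if (inherits(node, "xml_missing")) return(squish(fragment))
  squish(xml2::xml_text(node))
}

# Plain text of a node, excluding any descendant subtree that itself
# matches a paragraph selector (such subtrees become their own passages, so
# every text node under a paragraph selector lands in exactly one passage —
# tolerant parsers occasionally nest recovered elements inside an unclosed
# paragraph).
node_own_text <- function(node, config) {
  parts <- character(0)
  walk <- function(x) {
    for (ch in xml2::xml_contents(x)) {
      nm <- xml2::xml_name(ch)
      if (nm == "text") {
        parts[[length(parts) + 1L]] <<- xml2::xml_text(ch)
      } else if (nm %in% c("comment", "cdata")) {
        next
      } else {
        d <- list(tag = nm, attrs = as.list(xml2::xml_attrs(ch)))
        if (!is.null(match_scope(d, config, "paragraph"))) next
        walk(ch)
      }
    }
  }
  walk(node)
  squish(paste(parts, collapse = ""))
}

#' Derive a document id from a filename
#'
#' The filename stem is used; if a PMC accession pattern (`PMC` followed by
#' digits) occurs anywhere in the stem it is used verbatim.
#' @param path Input file path.
#' @return Character document id.
#' @export
document_id <- function(path) {
  stem <- tools::file_path_sans_ext(basename(path))
  m <- regmatches(stem, regexpr("PMC\\d+", stem))
  if (length(m) && nzchar(m)) m else stem
}

#' Parse full-text HTML into an article model
#'
#' Walks the document in reading order. Elements matching a heading selector
#' update the current heading path at the selector's depth (headings become
#' part of each passage's `heading_path`, never standalone passages);
#' elements matching a paragraph selector become passages with markup
#' stripped. Figure captions — paragraph matches inside a `<figure>`
#' element — are kept in reading order and flagged. Text inside matched
#' table containers is excluded (it belongs to the tables module). Parsing
#' is tolerant: malformed fragments are recovered, never fatal.
#'
#' @param html_text Full-text HTML as a single string.
#' @param config A `pubcorpus_config`.
#' @param doc_id Document identifier (defaults to "doc").
#' @return A `pubcorpus_article`: `document_id` plus an ordered list of
#'   passages, each `list(text, heading_path, is_caption)`. If nothing
#'   matches any selector an empty model is returned with a structured
#'   warning (the usual symptom of applying the wrong configuration).
#' @export
parse_article <- function(html_text, config, doc_id = "doc") {
  stopifnot(inherits(config, "pubcorpus_config"))
  doc <- xml2::read_html(enc2utf8(html_text))
  body <- xml2::xml_find_first(doc, "//body")
  passages <- list()
  heading_stack <- character(0)
  n_heading_hits <- 0L

  if (!inherits(body, "xml_missing")) {
    nodes <- xml2::xml_find_all(body, ".//*")
    paths <- vapply(nodes, xml2::xml_path, "")
    descrs <- lapply(nodes, function(nd)
      list(tag = xml2::xml_name(nd), attrs = as.list(xml2::xml_attrs(nd))))

    container_paths <- character(0)
    for (i in seq_along(nodes))
      if (!is.null(match_scope(descrs[[i]], config, "table_container")))
        container_paths <- c(container_paths, paths[i])
    in_container <- function(p)
      any(startsWith(p, paste0(container_paths, "/")) | p %in% container_paths)

    for (i in seq_along(nodes)) {
      p <- paths[i]
      if (length(container_paths) && in_container(p)) next
      d <- descrs[[i]]
      hsel <- match_scope(d, config, "heading")
      if (!is.null(hsel)) {
        lvl <- hsel$level
        txt <- strip_markup(as.character(nodes[[i]]))
        heading_stack <- heading_stack[seq_len(min(lvl - 1L,
                                                   length(heading_stack)))]
        heading_stack[lvl] <- txt
        n_heading_hits <- n_heading_hits + 1L
        next
      }
      psel <- match_scope(d, config, "paragraph")
      if (!is.null(psel)) {
        anc <- xml2::xml_find_all(nodes[[i]], "ancestor::*")
        is_cap <- any(vapply(anc, xml2::xml_name, "") == "figure")
        txt <- node_own_text(nodes[[i]], config)
        if (!nzchar(txt)) next
        hp <- heading_stack[!is.na(heading_stack) & nzchar(heading_stack)]
        passages[[length(passages) + 1L]] <-
          list(text = txt, heading_path = hp, is_caption = is_cap)
      }
    }
  }

  if (length(passages) == 0L && n_heading_hits == 0L)
    pc_warn("no heading or paragraph selector matched anything in '",
            doc_id, "': check the source configuration",
            class = "pubcorpus_empty_article")
  structure(list(document_id = doc_id, passages = passages),
            class = "pubcorpus_article")
}

#' @export
print.pubcorpus_article <- function(x, ...) {
  cat("<pubcorpus_article>", x$document_id, "-", length(x$passages),
      "passages\n")
  invisible(x)
}

#' Assemble a BioC collection from a classified article model
#'
#' Passage offsets are recomputed as cumulative UTF-8 code-point counts over
#' the passage texts retained in the collection, starting at 0. Passages
#' classified as the abbreviations section (IAO:0000606) are excluded here
#' (they are serialized by the abbreviations module); figure captions are
#' included inline in reading order. Heading paths are stored in infons as
#' `section_title_1`, `section_title_2`, ... and annotations as
#' `iao_name_1`/`iao_id_1`, ...
#'
#' @param model A `pubcorpus_article`.
#' @param classified Per-passage annotation list, aligned 1:1 with
#'   `model$passages`; each element a data.frame with columns `iao_name`,
#'   `iao_id` (zero rows allowed). Usually from [classify_sections()].
#' @param source Source label recorded in the collection.
#' @param date Date string recorded in the collection.
#' @return A `pubcorpus_bioc` collection.
#' @export
build_bioc <- function(model, classified, source = "pubcorpus",
                       date = format(Sys.Date(), "%Y%m%d")) {
  stopifnot(inherits(model, "pubcorpus_article"))
  if (length(classified) != length(model$passages))
    pc_stop("classification list is not aligned with passages (",
            length(classified), " vs ", length(model$passages), ")",
            class = "pubcorpus_internal_error")
  out <- list()
  offset <- 0L
  for (i in seq_along(model$passages)) {
    p <- model$passages[[i]]
    ann <- classified[[i]]
    if (!is.null(ann) && nrow(ann) && any(ann$iao_id == "IAO:0000606")) next
    infons <- list()
    for (k in seq_along(p$heading_path))
      infons[[paste0("section_title_", k)]] <- p$heading_path[k]
    if (!is.null(ann) && nrow(ann)) {
      for (k in seq_len(nrow(ann))) {
        infons[[paste0("iao_name_", k)]] <- ann$iao_name[k]
        infons[[paste0("iao_id_", k)]] <- ann$iao_id[k]
      }
    }
    out[[length(out) + 1L]] <- list(offset = offset, infons = infons,
                                    text = p$text)
    offset <- offset + n_codepoints(p$text)
  }
  structure(list(source = source, date = date, key = "pubcorpus_fulltext.key",
                 documents = list(list(id = model$document_id,
                                       passages = out))),
            class = "pubcorpus_bioc")
}

#' Write a BioC collection to JSON
#' @param collection A `pubcorpus_bioc`.
#' @param path Destination ( conventionally `<stem>_bioc.json`).
#' @return `path`, invisibly.
#' @export
write_bioc <- function(collection, path) {
  stopifnot(inherits(collection, "pubcorpus_bioc"))
  jsonlite::write_json(unclass(collection), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a BioC collection written by [write_bioc()]
#' @param path Path to a `*_bioc.json` file.
#' @return A `pubcorpus_bioc`.
#' @export
read_bioc <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  x$documents <- lapply(x$documents, function(d) {
    d$passages <- lapply(d$passages, function(p) {
      p$offset <- as.integer(p$offset)
      p
    })
    d
  })
  structure(x, class = "pubcorpus_bioc")
}

#' Structurally validate a BioC collection
#'
#' Checks the collection against the packaged full-text key: required
#' top-level fields, per-passage offset/infons/text fields, offset
#' arithmetic (cumulative code-point counts), and that every passage carries
#' a section title infon.
#' @param collection A `pubcorpus_bioc` (or the equivalent plain list).
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_bioc <- function(collection) {
  x <- unclass(collection)
  for (f in c("source", "date", "key", "documents"))
    if (is.null(x[[f]])) pc_stop("BioC collection missing field '", f, "'",
                                 class = "pubcorpus_schema_error")
  for (d in x$documents) {
    if (is.null(d$id)) pc_stop("BioC document missing 'id'",
                               class = "pubcorpus_schema_error")
    offset <- 0L
    for (p in d$passages) {
      for (f in c("offset", "infons", "text"))
        if (is.null(p[[f]]))
          pc_stop("BioC passage missing field '", f, "'",
                  class = "pubcorpus_schema_error")
      if (p$offset != offset)
        pc_stop("BioC offset mismatch: expected ", offset, ", found ",
                p$offset, class = "pubcorpus_schema_error")
      offset <- offset + n_codepoints(p$text)
    }
  }
  invisible(TRUE)
}
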