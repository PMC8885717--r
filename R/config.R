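#' Source configuration files
#'
#' A source configuration describes one publisher's HTML dialect: which
#' elements (optionally constrained by attribute values) delimit section
#' headings, paragraphs, and the parts of data tables. Regular expressions
#' are allowed both for element names (full match) and attribute values
#' (substring search), so one file can cover a family of journals whose
#' markup is similar but not identical.
#'
#' The file format is JSON:
#' \preformatted{
#' {
#'   "source": "fixture_dialect",
#'   "tables_mode": "inline",
#'   "contributors": ["A. Person"],
#'   "selectors": {
#'     "heading":   [{"element": "h1"}, {"element": "h2"}],
#'     "paragraph": [{"element": "p", "attrs": {"class": "para"}}],
#'     "table_container": [{"element": "div", "attrs": {"class": "table-wrap"}}]
#'   }
#' }
#' }
#' Heading selectors are ordered: the first selector denotes main headers,
#' the second sub-headers, and so on — their list position defines the
#' heading-hierarchy depth. Unknown top-level or selector keys are rejected
#' so that typos surface immediately.
#'
#' @name source-config
NULL

SELECTOR_SCOPES <- c("heading", "paragraph", "table_container", "table_title",
                     "table_caption", "table_footer", "linked_table_marker")

CONFIG_KEYS <- c("source", "tables_mode", "contributors", "selectors")

new_selector <- function(element, attrs = list(), scope, level = 1L) {
  if (!is.character(element) || length(element) != 1L || !nzchar(element))
    pc_stop("selector element name must be a non-empty string",
            class = "pubcorpus_config_error")
  if (!scope %in% SELECTOR_SCOPES)
    pc_stop("unknown selector scope: ", scope, class = "pubcorpus_config_error")
  check_regex(element)
  attrs <- as.list(attrs)
  if (length(attrs)) {
    if (is.null(names(attrs)) || any(!nzchar(names(attrs))))
      pc_stop("selector attribute constraints must be named",
              class = "pubcorpus_config_error")
    for (v in attrs) check_regex(as.character(v))
  }
  structure(list(element = element, attrs = attrs, scope = scope,
                 level = as.integer(level)),
            class = "pubcorpus_selector")
}

check_regex <- function(pattern) {
  ok <- tryCatch({ grepl(pattern, "", perl = TRUE); TRUE },
                 error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok)
    pc_stop("invalid regular expression in config: '", pattern, "'",
            class = "pubcorpus_config_error")
  invisible(pattern)
}

#' Load and validate a source configuration file
#'
#' @param path Path to a configuration JSON file.
#' @return A `pubcorpus_config` object: validated selectors grouped by scope,
#'   the source name, the tables mode (`"inline"`, `"linked"` or `"both"`),
#'   and the free-text contributor log.
#' @examples
#' cfg <- load_config(system.file("extdata/configs/fixture_dialect.json",
#'                                package = "pubcorpus"))
#' cfg$source
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    pc_stop("config file not found: ", path, class = "pubcorpus_io_error")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  as_config(raw, where = path)
}

#' Build a configuration from an R list (same shape as the JSON file)
#' @param x A list mirroring the config JSON structure.
#' @param where Label used in error messages.
#' @return A validated `pubcorpus_config`.
#' @export
as_config <- function(x, where = "<list>") {
  if (!is.list(x)) pc_stop("config must be a JSON object",
                           class = "pubcorpus_config_error")
  extra <- setdiff(names(x), CONFIG_KEYS)
  if (length(extra))
    pc_stop("unknown config key(s): ", paste(extra, collapse = ", "),
            class = "pubcorpus_config_error")
  if (is.null(x$selectors) || !is.list(x$selectors))
    pc_stop("config key 'selectors' missing", class = "pubcorpus_config_error")
  bad_scope <- setdiff(names(x$selectors), SELECTOR_SCOPES)
  if (length(bad_scope))
    pc_stop("unknown selector scope(s): ", paste(bad_scope, collapse = ", "),
            class = "pubcorpus_config_error")

  sels <- list()
  for (scope in names(x$selectors)) {
    entries <- x$selectors[[scope]]
    sels[[scope]] <- lapply(seq_along(entries), function(i) {
      e <- entries[[i]]
      extra <- setdiff(names(e), c("element", "attrs"))
      if (length(extra))
        pc_stop("unknown selector key(s) under '", scope, "': ",
                paste(extra, collapse = ", "), class = "pubcorpus_config_error")
      new_selector(e$element, e$attrs %||% list(), scope, level = i)
    })
  }
  if (length(sels$heading %||% list()) == 0L)
    pc_stop("config must declare at least one heading selector",
            class = "pubcorpus_config_error")
  if (length(sels$paragraph %||% list()) == 0L)
    pc_stop("config must declare at least one paragraph selector",
            class = "pubcorpus_config_error")

  tables_mode <- x$tables_mode %||% "inline"
  if (!tables_mode %in% c("inline", "linked", "both"))
    pc_stop("tables_mode must be one of inline/linked/both",
            class = "pubcorpus_config_error")
  if (tables_mode %in% c("linked", "both") &&
      length(sels$table_container %||% list()) == 0L)
    pc_stop("tables_mode '", tables_mode,
            "' requires table_container selectors",
            class = "pubcorpus_config_error")

  structure(list(source = x$source %||% tools::file_path_sans_ext(basename(where)),
                 tables_mode = tables_mode,
                 contributors = unlist(x$contributors %||% character(0)),
                 selectors = sels),
            class = "pubcorpus_config")
}

#' Serialize a configuration back to its JSON form
#' @param config A `pubcorpus_config`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pubcorpus_config"))
  sel <- lapply(config$selectors, function(entries)
    lapply(entries, function(s) {
      out <- list(element = s$element)
      if (length(s$attrs)) out$attrs <- s$attrs
      out
    }))
  obj <- list(source = config$source, tables_mode = config$tables_mode,
              contributors = as.list(config$contributors), selectors = sel)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Test whether an HTML node matches a selector
#'
#' Element names are matched in full (the pattern is anchored); attribute
#' value patterns are searched as substrings, since publisher class
#' attributes routinely carry generated suffixes. Total and deterministic:
#' the same node and selector always give the same answer.
#'
#' @param node A list with `tag` (string) and `attrs` (named character
#'   vector/list), or an `xml2` node.
#' @param selector A selector as found in `config$selectors[[scope]]`.
#' @return `TRUE` or `FALSE`.
#' @export
node_matches <- function(node, selector) {
  if (inherits(node, "xml_node"))
    node <- list(tag = xml2::xml_name(node), attrs = as.list(xml2::xml_attrs(node)))
  tag <- node$tag
  if (is.null(tag) || !grepl(paste0("^(?:", selector$element, ")$"), tag,
                             perl = TRUE))
    return(FALSE)
  for (a in names(selector$attrs)) {
    v <- node$attrs[[a]]
    if (is.null(v) || is.na(v)) return(FALSE)
    if (!grepl(as.character(selector$attrs[[a]]), v, perl = TRUE)) return(FALSE)
  }
  TRUE
}

# First matching selector of a scope, or NULL. Returns the selector (its
# $level encodes heading depth).
match_scope <- function(node, config, scope) {
  for (s in config$selectors[[scope]] %||% list())
    if (node_matches(node, s)) return(s)
  NULL
}

#' @export
print.pubcorpus_config <- function(x, ...) {
  cat("<pubcorpus_config> source:", x$source, "| tables_mode:", x$tables_mode, "\n")
  for (scope in names(x$selectors))
    cat("  ", scope, ": ",
        paste(vapply(x$selectors[[scope]], function(s) s$element, ""),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}
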