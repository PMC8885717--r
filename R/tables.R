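#' Structural analysis of publication data tables
#'
#' Data tables (as opposed to layout tables, which the configuration's
#' `table_container` selectors exclude) are expanded into rectangular grids
#' (row/column spans replicated into every covered slot), their navigational
#' cells identified, and their content emitted in a table JSON format:
#' metadata (title, caption, footer), pipe-joined multi-row column headers,
#' data rows grouped into named sections by super rows or an index (stub)
#' column, and sub-tables split out wherever a row re-declares column
#' headers mid-body. Every column header and data cell carries a stable
#' identifier usable in stand-off annotations.
#'
#' @name tables
NULL

SUP_OPEN <- "\uE000"
SUP_CLOSE <- "\uE001"

# Inner HTML of a node as a string.
inner_html <- function(node) {
  kids <- xml2::xml_contents(node)
  if (length(kids) == 0L) return("")
  paste(vapply(kids, as.character, ""), collapse = "")
}

# Unicode superscript characters (e.g. 10⁻⁸) are treated like <sup> markup
# in the numeric path: runs are wrapped in the sentinels and translated to
# their ASCII counterparts.
mark_unicode_sup <- function(x) {
  cls <- "[\u2070\u00b9\u00b2\u00b3\u2074-\u2079\u207a\u207b]+"
  x <- gsub(paste0("(", cls, ")"), paste0(SUP_OPEN, "\\1", SUP_CLOSE), x)
  chartr(paste0("\u2070\u00b9\u00b2\u00b3\u2074\u2075\u2076\u2077\u2078",
                "\u2079\u207a\u207b"),
         "0123456789+-", x)
}

# Plain cell text with superscript segments preserved as explicit
# " <sup>x</sup>" markup (all other formatting removed).
cell_text_with_sup <- function(raw) {
  x <- gsub("<\\s*sup[^>]*>", SUP_OPEN, raw)
  x <- gsub("<\\s*/\\s*sup\\s*>", SUP_CLOSE, x)
  x <- strip_markup(x)
  x <- gsub(SUP_OPEN, " <sup>", x, fixed = TRUE)
  x <- gsub(SUP_CLOSE, "</sup>", x, fixed = TRUE)
  squish(x)
}

#' Parse one raw table cell into a number or a string
#'
#' Cells containing only a (signed, decimal) number become JSON numbers;
#' cells containing only scientific notation — `a x 10^b` with a
#' superscripted exponent, or E-notation — are converted to exponential
#' numbers. The Unicode minus sign and an en dash used as a minus are
#' accepted inside numbers, as are the multiplication sign and the letter
#' x. "true"/"false" stay strings. Any other content becomes a string with
#' formatting removed, except superscript, which is re-encoded as explicit
#' `<sup>` markup so that positive exponents inside text keep their meaning
#' (e.g. `n = 10 <sup>3</sup>`). Cells with thousands-separator commas are
#' not numbers. Empty cells become empty strings.
#'
#' @param raw Inner HTML (or plain text) of one table cell.
#' @return A numeric scalar or a character scalar.
#' @examples
#' parse_cell("5 × 10<sup>−8</sup>")  # 5e-08
#' parse_cell("true")                           # "true"
#' parse_cell("n = 10<sup>3</sup>")             # "n = 10 <sup>3</sup>"
#' @export
parse_cell <- function(raw) {
  if (is.null(raw) || is.na(raw)) return("")
  plain <- strip_markup(raw)
  if (!nzchar(plain)) return("")
  if (tolower(plain) %in% c("true", "false")) return(plain)

  dashes_to_minus <- function(x) gsub("[−–]", "-", x)
  num_re <- "[+-]?[0-9]*\\.?[0-9]+"
  plain_m <- dashes_to_minus(plain)
  if (grepl(paste0("^", num_re, "$"), plain_m))
    return(as.numeric(plain_m))

  # scientific notation: E-notation on the flat text ...
  if (grepl(paste0("^", num_re, "[eE]", "[+-]?[0-9]+$"), plain_m))
    return(as.numeric(plain_m))
  # ... or a x 10^b with a superscripted exponent
  marked <- gsub("<\\s*sup[^>]*>", SUP_OPEN, raw)
  marked <- gsub("<\\s*/\\s*sup\\s*>", SUP_CLOSE, marked)
  marked <- squish(dashes_to_minus(mark_unicode_sup(strip_markup(marked))))
  sci_re <- paste0("^(", num_re, ") ?[x×X*] ?10 ?",
                   SUP_OPEN, " ?([+-]?[0-9]+) ?", SUP_CLOSE, "$")
  m <- regmatches(marked, regexec(sci_re, marked))[[1]]
  if (length(m) == 3L)
    return(as.numeric(m[2]) * 10^as.numeric(m[3]))

  cell_text_with_sup(raw)
}

#' Expand an HTML table element into a rectangular grid
#'
#' Row and column spans are expanded so every logical slot holds a cell;
#' spanned source cells are replicated into each covered slot (the source
#' cell identity is retained so super rows and stub cells can be
#' recognized).
#'
#' @param table_node An `xml2` node for a `<table>` element.
#' @return A `pubcorpus_grid`: source-cell list and an occupancy matrix of
#'   source-cell indices (0 = empty slot).
#' @export
extract_grid <- function(table_node) {
  trs <- xml2::xml_find_all(table_node, ".//tr")
  cells <- list()
  occ <- list()
  for (r in seq_along(trs)) {
    if (length(occ) < r) occ[[r]] <- integer(0)
    tds <- xml2::xml_find_all(trs[[r]], "./td|./th")
    cp <- 1L
    for (td in tds) {
      while (cp <= length(occ[[r]]) && occ[[r]][cp] != 0L) cp <- cp + 1L
      rs <- suppressWarnings(as.integer(xml2::xml_attr(td, "rowspan")))
      cs <- suppressWarnings(as.integer(xml2::xml_attr(td, "colspan")))
      rs <- max(1L, if (is.na(rs)) 1L else rs)
      cs <- max(1L, if (is.na(cs)) 1L else cs)
      anc <- vapply(xml2::xml_find_all(td, "ancestor::*"), xml2::xml_name, "")
      idx <- length(cells) + 1L
      cells[[idx]] <- list(html = inner_html(td),
                           is_th = xml2::xml_name(td) == "th" ||
                             "thead" %in% anc,
                           rowspan = rs, colspan = cs, row = r, col = cp)
      for (rr in r:(r + rs - 1L)) {
        if (length(occ) < rr) occ[[rr]] <- integer(0)
        if (length(occ[[rr]]) < cp + cs - 1L)
          occ[[rr]][(length(occ[[rr]]) + 1L):(cp + cs - 1L)] <- 0L
        occ[[rr]][cp:(cp + cs - 1L)] <- idx
      }
      cp <- cp + cs
    }
  }
  nc <- max(c(0L, lengths(occ)))
  mat <- matrix(0L, nrow = length(occ), ncol = nc)
  for (r in seq_along(occ))
    if (length(occ[[r]])) mat[r, seq_along(occ[[r]])] <- occ[[r]]
  structure(list(cells = cells, occ = mat), class = "pubcorpus_grid")
}

grid_nrow <- function(grid) nrow(grid$occ)
grid_ncol <- function(grid) ncol(grid$occ)

# Raw inner HTML at slot (r, c); "" for empty slots.
grid_html <- function(grid, r, c) {
  i <- grid$occ[r, c]
  if (i == 0L) "" else grid$cells[[i]]$html
}

grid_plain <- function(grid, r, c) strip_markup(grid_html(grid, r, c))

# Number of leading header rows: rows whose non-empty cells carry header
# markup (<th> or <thead>); if the table has none at all, the first row is
# taken as the header row.
header_row_count <- function(grid) {
  nr <- grid_nrow(grid)
  if (nr == 0L) return(0L)
  h <- 0L
  for (r in seq_len(nr)) {
    ids <- setdiff(unique(grid$occ[r, ]), 0L)
    if (length(ids) && all(vapply(grid$cells[ids], `[[`, TRUE, "is_th")))
      h <- h + 1L
    else break
  }
  if (h == 0L) 1L else h
}

#' Resolve column headers of a grid
#'
#' The leading navigational rows become column headers; where a column's
#' header is split across several rows the strings are concatenated
#' top-to-bottom with a pipe separator, and text from a cell spanning
#' several columns is replicated into each covered column (once per
#' column, however many rows it spans).
#'
#' @param grid A `pubcorpus_grid`.
#' @return `list(headers, n_header_rows, body_rows)`: the pipe-joined
#'   header strings, the number of header rows consumed, and the body row
#'   indices. A headerless grid yields empty headers with a warning.
#' @export
resolve_headers <- function(grid) {
  nr <- grid_nrow(grid); nc <- grid_ncol(grid)
  if (nr == 0L || nc == 0L) {
    pc_warn("empty table grid", class = "pubcorpus_headerless_table")
    return(list(headers = character(0), n_header_rows = 0L,
                body_rows = integer(0)))
  }
  h <- header_row_count(grid)
  headers <- character(nc)
  for (c in seq_len(nc)) {
    parts <- character(0)
    last_src <- 0L
    for (r in seq_len(h)) {
      i <- grid$occ[r, c]
      if (i == 0L || i == last_src) next
      txt <- strip_markup(grid$cells[[i]]$html)
      if (nzchar(txt)) parts <- c(parts, txt)
      last_src <- i
    }
    headers[c] <- paste(parts, collapse = "|")
  }
  body <- if (h < nr) (h + 1L):nr else integer(0)
  if (all(!nzchar(headers)))
    pc_warn("table has no recognizable header row",
            class = "pubcorpus_headerless_table")
  list(headers = headers, n_header_rows = h, body_rows = body)
}

# A body row is a super row when all its non-empty slots come from a single
# source cell spanning the full grid width.
is_super_row <- function(grid, r) {
  ids <- setdiff(unique(grid$occ[r, ]), 0L)
  length(ids) == 1L &&
    all(grid$occ[r, ] == ids) &&
    nzchar(strip_markup(grid$cells[[ids]]$html))
}

#' Classify body columns as numerical, textual or mixed
#'
#' Per cell: numerical iff [parse_cell()] yields a number; textual iff the
#' text contains no digits; mixed otherwise. The column type is the modal
#' cell type over the given rows excluding super rows; ties break to mixed;
#' a column with no informative cells is textual by convention.
#'
#' @param grid A `pubcorpus_grid`.
#' @param rows Body row indices to consider.
#' @param super Logical mask (aligned with `rows`) of super rows.
#' @return Character vector of column types.
#' @export
classify_columns <- function(grid, rows, super = rep(FALSE, length(rows))) {
  nc <- grid_ncol(grid)
  types <- character(nc)
  use <- rows[!super]
  for (c in seq_len(nc)) {
    tt <- vapply(use, function(r) cell_type(grid_html(grid, r, c)), "")
    tab <- table(tt[tt != "empty"])
    if (length(tab) == 0L) { types[c] <- "textual"; next }
    best <- names(tab)[tab == max(tab)]
    types[c] <- if (length(best) > 1L) "mixed" else best
  }
  types
}

cell_type <- function(raw) {
  v <- parse_cell(raw)
  if (is.numeric(v)) return("numerical")
  if (!nzchar(v)) return("empty")
  if (!grepl("[0-9]", v)) return("textual")
  "mixed"
}

#' Split a table body into sub-table blocks
#'
#' Scanning non-super body rows top-down against the column types derived
#' from the current block, a row in which strictly more than half of the
#' cells mismatch their column's type is taken as a new header row; the
#' rows that follow form a sub-table (whose column types are re-derived).
#' The k-th split receives the identifier suffix `_k`.
#'
#' @param grid A `pubcorpus_grid`.
#' @param body_rows Body row indices.
#' @return List of blocks `list(header_row, rows)`; the first block has
#'   `header_row = NA` (it uses the table's own resolved headers).
#' @export
split_subtables <- function(grid, body_rows) {
  blocks <- list()
  remaining <- body_rows
  hdr <- NA_integer_
  nc <- grid_ncol(grid)
  while (TRUE) {
    if (length(remaining) == 0L) {
      blocks[[length(blocks) + 1L]] <- list(header_row = hdr,
                                            rows = integer(0))
      break
    }
    super <- vapply(remaining, function(r) is_super_row(grid, r), TRUE)
    types <- classify_columns(grid, remaining, super)
    split_at <- NA_integer_
    for (k in seq_along(remaining)) {
      if (super[k]) next
      r <- remaining[k]
      tt <- vapply(seq_len(nc), function(c)
        cell_type(grid_html(grid, r, c)), "")
      mism <- sum(tt != "empty" & tt != types)
      if (mism > nc / 2) { split_at <- k; break }
    }
    if (is.na(split_at)) {
      blocks[[length(blocks) + 1L]] <- list(header_row = hdr,
                                            rows = remaining)
      break
    }
    blocks[[length(blocks) + 1L]] <-
      list(header_row = hdr, rows = remaining[seq_len(split_at - 1L)])
    hdr <- remaining[split_at]
    remaining <- remaining[-seq_len(split_at)]
  }
  blocks
}

#' Group body rows into named sections
#'
#' A super row (single source cell spanning the complete row) closes the
#' previous section and names the next. Alternatively, when the first
#' column has no header and contains cells spanning several rows, it is
#' treated as an index (stub) column: each stub cell names the section
#' formed by the rows it covers, and the stub column is consumed (dropped
#' from the data rows). Rows before any divider form an unnamed section.
#'
#' @param grid A `pubcorpus_grid`.
#' @param rows Body row indices of one block.
#' @param headers Column headers of the block.
#' @return `list(sections, headers)`: sections are `list(name, rows,
#'   drop_first_col)`; headers are returned (minus the stub column in stub
#'   mode).
#' @export
segment_sections <- function(grid, rows, headers) {
  stub_mode <- length(headers) > 0L && !nzchar(headers[1L]) &&
    any(vapply(rows, function(r) {
      i <- grid$occ[r, 1L]
      i != 0L && grid$cells[[i]]$rowspan > 1L
    }, TRUE))

  sections <- list()
  if (stub_mode) {
    cur_src <- -1L
    for (r in rows) {
      i <- grid$occ[r, 1L]
      if (i != cur_src) {
        nm <- if (i == 0L) "" else strip_markup(grid$cells[[i]]$html)
        sections[[length(sections) + 1L]] <-
          list(name = nm, rows = integer(0))
        cur_src <- i
      }
      k <- length(sections)
      sections[[k]]$rows <- c(sections[[k]]$rows, r)
    }
    return(list(sections = sections, headers = headers[-1L],
                drop_first_col = TRUE))
  }

  cur <- list(name = "", rows = integer(0))
  opened <- FALSE
  for (r in rows) {
    if (is_super_row(grid, r)) {
      if (opened || length(cur$rows))
        sections[[length(sections) + 1L]] <- cur
      i <- setdiff(unique(grid$occ[r, ]), 0L)
      cur <- list(name = strip_markup(grid$cells[[i]]$html),
                  rows = integer(0))
      opened <- TRUE
    } else {
      cur$rows <- c(cur$rows, r)
    }
  }
  if (opened || length(cur$rows)) sections[[length(sections) + 1L]] <- cur
  list(sections = sections, headers = headers, drop_first_col = FALSE)
}

# Assemble one TableDocument from a block of rows.
block_to_document <- function(grid, identifier, headers, rows, meta) {
  seg <- segment_sections(grid, rows, headers)
  nc_all <- grid_ncol(grid)
  col_idx <- if (seg$drop_first_col) seq_len(nc_all)[-1L] else seq_len(nc_all)
  prefix <- paste0("T", identifier)
  column_headers <- data.frame(
    cell_id = paste0(prefix, ".C", seq_along(col_idx)),
    text = seg$headers, stringsAsFactors = FALSE)
  sections <- lapply(seq_along(seg$sections), function(s) {
    sec <- seg$sections[[s]]
    rws <- lapply(seq_along(sec$rows), function(k) {
      r <- sec$rows[k]
      lapply(seq_along(col_idx), function(ci)
        list(cell_id = paste0(prefix, ".S", s, ".R", k, ".C", ci),
             value = parse_cell(grid_html(grid, r, col_idx[ci]))))
    })
    list(name = sec$name, rows = rws)
  })
  structure(list(identifier = identifier, title = meta$title,
                 caption = meta$caption, footer = meta$footer,
                 column_headers = column_headers, sections = sections),
            class = "pubcorpus_table")
}

#' Analyze one expanded grid into TableDocuments
#'
#' Runs header resolution, sub-table splitting, section segmentation and
#' cell parsing. Sub-tables carry metadata identical to the parent and
#' identifiers `"N_1"`, `"N_2"`, ... in scan order.
#'
#' @param grid A `pubcorpus_grid`.
#' @param identifier Parent table identifier (e.g. `"1"`).
#' @param title,caption,footer Metadata strings (may be `""`).
#' @return List of `pubcorpus_table` documents (parent first).
#' @export
analyze_grid <- function(grid, identifier = "1", title = "", caption = "",
                         footer = "") {
  meta <- list(title = title, caption = caption, footer = footer)
  rh <- resolve_headers(grid)
  if (length(rh$body_rows) == 0L && length(rh$headers) == 0L)
    return(list(block_to_document(grid, identifier, character(0),
                                  integer(0), meta)))
  blocks <- split_subtables(grid, rh$body_rows)
  out <- list()
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    id <- if (b == 1L) identifier else paste0(identifier, "_", b - 1L)
    headers <- if (is.na(blk$header_row)) rh$headers
      else vapply(seq_len(grid_ncol(grid)), function(c)
        grid_plain(grid, blk$header_row, c), "")
    out[[b]] <- block_to_document(grid, id, headers, blk$rows, meta)
  }
  out
}

#' Locate data tables in an HTML document
#'
#' Only elements matching the configuration's `table_container` selectors
#' are returned, so layout tables are excluded. The table number is parsed
#' from the title text ("Table N"), falling back to the container's
#' position.
#'
#' @param html_text HTML string (full text for inline mode; a one-table
#'   file for linked mode).
#' @param config A `pubcorpus_config`.
#' @param mode `"inline"` or `"linked"`.
#' @return List of `list(grid, identifier, title, caption, footer)`.
#' @export
locate_tables <- function(html_text, config, mode = c("inline", "linked")) {
  mode <- match.arg(mode)
  doc <- xml2::read_html(enc2utf8(html_text))
  nodes <- xml2::xml_find_all(doc, "//body//*")
  out <- list()
  for (nd in nodes) {
    d <- list(tag = xml2::xml_name(nd), attrs = as.list(xml2::xml_attrs(nd)))
    if (is.null(match_scope(d, config, "table_container"))) next
    tbl <- if (d$tag == "table") nd
      else xml2::xml_find_first(nd, ".//table")
    if (inherits(tbl, "xml_missing")) next
    meta <- list(title = "", caption = "", footer = "")
    for (scope in c("table_title", "table_caption", "table_footer")) {
      key <- sub("table_", "", scope)
      for (sub_nd in xml2::xml_find_all(nd, ".//*")) {
        sd <- list(tag = xml2::xml_name(sub_nd),
                   attrs = as.list(xml2::xml_attrs(sub_nd)))
        if (!is.null(match_scope(sd, config, scope))) {
          meta[[key]] <- strip_markup(as.character(sub_nd))
          break
        }
      }
    }
    num <- regmatches(meta$title, regexec("Table[[:space:]]*([0-9]+)",
                                          meta$title))[[1]]
    identifier <- if (length(num) == 2L) num[2] else
      as.character(length(out) + 1L)
    out[[length(out) + 1L]] <- list(grid = extract_grid(tbl),
                                    identifier = identifier,
                                    title = meta$title,
                                    caption = meta$caption,
                                    footer = meta$footer)
  }
  if (mode == "linked" && length(out) == 0L)
    pc_warn("linked-table file contains no matching table container",
            class = "pubcorpus_no_tables")
  out
}

#' Process all data tables of an HTML document into TableDocuments
#' @inheritParams locate_tables
#' @return List of `pubcorpus_table` documents (sub-tables as siblings of
#'   their parent).
#' @export
process_tables <- function(html_text, config, mode = c("inline", "linked")) {
  mode <- match.arg(mode)
  located <- locate_tables(html_text, config, mode)
  out <- list()
  for (t in located)
    out <- c(out, analyze_grid(t$grid, t$identifier, t$title, t$caption,
                               t$footer))
  out
}

table_to_json_obj <- function(tab) {
  list(identifier = tab$identifier,
       metadata = list(
         list(section_type = "table_title", text = tab$title),
         list(section_type = "table_caption", text = tab$caption),
         list(section_type = "table_footer", text = tab$footer)),
       column_headers = lapply(seq_len(nrow(tab$column_headers)), function(i)
         list(cell_id = tab$column_headers$cell_id[i],
              text = tab$column_headers$text[i])),
       sections = lapply(tab$sections, function(s)
         list(name = s$name, rows = s$rows)))
}

#' Write TableDocuments to the table JSON format
#'
#' One file per article (conventional suffix `_tables.json`). Metadata is
#' stored as three passages with the section-type labels `table_title`,
#' `table_caption` and `table_footer`. Duplicate identifiers are an error.
#'
#' @param tables List of `pubcorpus_table`.
#' @param path Destination file.
#' @param doc_id Article identifier.
#' @param source,date Collection-level provenance strings.
#' @return `path`, invisibly.
#' @export
build_table_json <- function(tables, path, doc_id = "doc",
                             source = "pubcorpus",
                             date = format(Sys.Date(), "%Y%m%d")) {
  ids <- vapply(tables, `[[`, "", "identifier")
  if (anyDuplicated(ids))
    pc_stop("duplicate table identifiers: ",
            paste(ids[duplicated(ids)], collapse = ", "),
            class = "pubcorpus_table_error")
  obj <- list(source = source, date = date, key = "pubcorpus_tables.key",
              documents = list(list(id = doc_id,
                                    tables = lapply(tables,
                                                    table_to_json_obj))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a table JSON file back into TableDocuments
#' @param path Path to a `*_tables.json` file.
#' @return `list(doc_id, tables)` where `tables` is a list of
#'   `pubcorpus_table`.
#' @export
read_table_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc <- x$documents[[1]]
  tables <- lapply(doc$tables, function(t) {
    meta <- setNames(
      lapply(t$metadata, `[[`, "text"),
      vapply(t$metadata, `[[`, "", "section_type"))
    ch <- data.frame(
      cell_id = vapply(t$column_headers, `[[`, "", "cell_id"),
      text = vapply(t$column_headers, `[[`, "", "text"),
      stringsAsFactors = FALSE)
    structure(list(identifier = t$identifier,
                   title = meta[["table_title"]] %||% "",
                   caption = meta[["table_caption"]] %||% "",
                   footer = meta[["table_footer"]] %||% "",
                   column_headers = ch,
                   sections = lapply(t$sections, function(s)
                     list(name = s$name, rows = s$rows))),
              class = "pubcorpus_table")
  })
  list(doc_id = doc$id, tables = tables)
}

#' Structurally validate a table JSON file or object
#' @param x Path to a table JSON file, or the parsed object.
#' @return `TRUE` invisibly; errors name the first violation.
#' @export
validate_table_json <- function(x) {
  if (is.character(x)) x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  for (f in c("source", "date", "key", "documents"))
    if (is.null(x[[f]])) pc_stop("table JSON missing field '", f, "'",
                                 class = "pubcorpus_schema_error")
  for (d in x$documents) {
    for (t in d$tables) {
      if (is.null(t$identifier))
        pc_stop("table entry missing 'identifier'",
                class = "pubcorpus_schema_error")
      labs <- vapply(t$metadata, `[[`, "", "section_type")
      if (!all(c("table_title", "table_caption", "table_footer") %in% labs))
        pc_stop("table ", t$identifier, " missing metadata section types",
                class = "pubcorpus_schema_error")
      arity <- length(t$column_headers)
      ids <- vapply(t$column_headers, `[[`, "", "cell_id")
      for (s in t$sections) for (row in s$rows) {
        if (length(row) != arity)
          pc_stop("table ", t$identifier, " row arity ", length(row),
                  " != header count ", arity,
                  class = "pubcorpus_schema_error")
        ids <- c(ids, vapply(row, `[[`, "", "cell_id"))
      }
      if (anyDuplicated(ids))
        pc_stop("duplicate cell ids in table ", t$identifier,
                class = "pubcorpus_schema_error")
    }
  }
  invisible(TRUE)
}

#' @export
print.pubcorpus_table <- function(x, ...) {
  cat("<pubcorpus_table>", x$identifier, "-",
      nrow(x$column_headers), "columns,",
      sum(vapply(x$sections, function(s) length(s$rows), 0L)), "rows in",
      length(x$sections), "section(s)\n")
  invisible(x)
}
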