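#' Synthetic publisher-style fixtures with exact ground truth
#'
#' Generates article and table HTML in a small documented dialect (plus a
#' "messy" variant with unclosed tags and span-wrapped text, to exercise
#' tolerant parsing), together with byte-exact ground-truth BioC, table and
#' abbreviation structures, so every pipeline stage can be validated
#' without downloading anything. Generation is fully deterministic under
#' the spec's seed.
#'
#' @name fixtures
NULL

FIXTURE_VOCAB <- c(
  "cohort", "signal", "variant", "analysis", "model", "plasma", "profile",
  "measurement", "association", "phenotype", "pathway", "cluster", "score",
  "baseline", "replication", "marker", "subject", "tissue", "spectrum",
  "assay", "control", "effect", "estimate", "sample", "feature", "region",
  "outcome", "ratio", "level", "study")

# Evaluate code under a deterministic RNG state, restoring the caller's.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

rand_sentence <- function(n_words) {
  w <- sample(FIXTURE_VOCAB, n_words, replace = TRUE)
  w[1] <- paste0(toupper(substr(w[1], 1, 1)), substr(w[1], 2, nchar(w[1])))
  paste0(paste(w, collapse = " "), ".")
}

rand_paragraph <- function() {
  paste(vapply(seq_len(sample(2:4, 1)), function(i)
    rand_sentence(sample(6:12, 1)), ""), collapse = " ")
}

#' Specify a synthetic article
#'
#' @param seed Integer; fully determines the generated bytes.
#' @param sections List of `list(header, mode, truth, subs)`: `mode` is
#'   `"lexical"` (header is a lexicon synonym), `"typo"` (a <=2-edit
#'   perturbation of the header is emitted, kept at fuzzy ratio >= 0.8) or
#'   `"unmapped"` (a header absent from the lexicon is emitted; `truth`
#'   must give the IAO id the digraph should recover). `subs` is an
#'   optional character vector of sub-headers (each classified on its own,
#'   lexicon synonyms or free text).
#' @param abbrevs List of `list(short, long, placement, fulltext_long)`
#'   with placement in fulltext/section/both; `fulltext_long` optionally
#'   varies the full-text definition (the abbreviations section keeps
#'   `long`).
#' @param tables List of table specs from [table_spec()] (rendered inline).
#' @param id Document id.
#' @param dialect `"clean"` or `"messy"` (unclosed `<p>` tags, `<span>`
#'   wrappers).
#' @param figure Insert a figure caption passage into the last section.
#' @param quirks List of flags: `unicode_dashes`, `greek` inject the
#'   corresponding character classes into paragraph text.
#' @return An `article_spec` list.
#' @export
article_spec <- function(seed, sections, abbrevs = list(), tables = list(),
                         id = paste0("SYN", seed), dialect = "clean",
                         figure = FALSE,
                         quirks = list(unicode_dashes = FALSE,
                                       greek = FALSE)) {
  stopifnot(length(sections) >= 1L, dialect %in% c("clean", "messy"))
  sections <- lapply(sections, function(s) {
    s$mode <- s$mode %||% "lexical"
    stopifnot(s$mode %in% c("lexical", "typo", "unmapped"))
    if (s$mode == "unmapped" && is.null(s$truth))
      pc_stop("unmapped section needs a 'truth' IAO id",
              class = "pubcorpus_fixture_error")
    s$subs <- s$subs %||% character(0)
    s
  })
  for (a in abbrevs)
    stopifnot(a$placement %in% c("fulltext", "section", "both"))
  structure(list(seed = seed, sections = sections, abbrevs = abbrevs,
                 tables = tables, id = id, dialect = dialect,
                 figure = figure,
                 quirks = modifyList(list(unicode_dashes = FALSE,
                                          greek = FALSE), quirks)),
            class = "pubcorpus_article_spec")
}

# Deterministic <=2-edit typo keeping the fuzzy ratio above threshold:
# swaps an adjacent letter pair (avoiding word boundaries where possible).
make_typo <- function(header, threshold = 0.8) {
  chars <- strsplit(header, "")[[1]]
  norm0 <- normalize_header(header)
  cand_pos <- which(grepl("[[:alpha:]]", chars[-length(chars)]) &
                      grepl("[[:alpha:]]", chars[-1]) &
                      chars[-length(chars)] != chars[-1])
  for (p in rev(cand_pos)) {
    sw <- chars
    sw[c(p, p + 1L)] <- sw[c(p + 1L, p)]
    typo <- paste(sw, collapse = "")
    nt <- normalize_header(typo)
    if (identical(nt, norm0)) next
    if (lcs_ratio(nt, norm0) >= threshold) return(typo)
  }
  pc_stop("cannot build a typo for '", header,
          "' that stays above the fuzzy threshold",
          class = "pubcorpus_fixture_error")
}

wrap_para <- function(text, dialect, class = "para") {
  if (dialect == "messy") {
    # unclosed <p>, text partially wrapped in spans
    words <- tokenize_words(text)
    k <- max(1L, length(words) %/% 2L)
    paste0("<p class='", class, "'>",
           paste(words[seq_len(k)], collapse = " "),
           " <span class='x'>",
           paste(words[-seq_len(k)], collapse = " "), "</span>")
  } else {
    paste0("<p class='", class, "'>", text, "</p>")
  }
}

# Internal: realize section headers, paragraph texts and plants for a spec.
realize_article <- function(spec, lexicon) {
  with_seed(spec$seed, {
    secs <- list()
    for (i in seq_along(spec$sections)) {
      s <- spec$sections[[i]]
      header_out <- switch(s$mode,
        lexical = s$header,
        typo = make_typo(s$header),
        unmapped = s$header)
      if (s$mode == "lexical" && is.na(match_lexical(s$header, lexicon)))
        pc_stop("fixture header '", s$header, "' is not a lexicon synonym",
                class = "pubcorpus_fixture_error")
      if (s$mode == "unmapped" && !is.na(match_lexical(s$header, lexicon)))
        pc_stop("fixture header '", s$header,
                "' is supposed to be unmapped but is in the lexicon",
                class = "pubcorpus_fixture_error")
      truth_id <- switch(s$mode,
        lexical = match_lexical(s$header, lexicon),
        typo = match_lexical(s$header, lexicon),
        unmapped = s$truth)
      paras <- vapply(seq_len(sample(1:2, 1)), function(k)
        rand_paragraph(), "")
      if (spec$quirks$unicode_dashes)
        paras[1] <- sub("\\.$", " – range 1–2.", paras[1])
      if (spec$quirks$greek)
        paras[1] <- sub("\\.$", " (β coefficient).", paras[1])
      subs <- lapply(s$subs, function(sh)
        list(header = sh, text = rand_paragraph()))
      secs[[i]] <- list(header = s$header, header_out = header_out,
                        mode = s$mode, truth_id = truth_id,
                        paras = paras, subs = subs)
    }

    # plant full-text abbreviation sentences round-robin over sections
    ft <- Filter(function(a) a$placement %in% c("fulltext", "both"),
                 spec$abbrevs)
    for (k in seq_along(ft)) {
      a <- ft[[k]]
      long <- a$fulltext_long %||% a$long
      tgt <- ((k - 1L) %% length(secs)) + 1L
      secs[[tgt]]$paras[1] <- paste0(
        secs[[tgt]]$paras[1], " The ", long, " (", a$short,
        ") was assessed.")
    }
    sect <- Filter(function(a) a$placement %in% c("section", "both"),
                   spec$abbrevs)
    abbrev_text <- if (length(sect))
      paste(vapply(sect, function(a) paste0(a$short, ": ", a$long), ""),
            collapse = "; ")
    else NULL
    fig_text <- if (spec$figure)
      paste("Figure 1", rand_sentence(6)) else NULL
    list(secs = secs, abbrev_text = abbrev_text, fig_text = fig_text)
  })
}

#' Generate a synthetic article with ground truth
#'
#' @param spec An [article_spec()].
#' @param lexicon A `pubcorpus_lexicon` (defaults to the packaged one).
#' @return List with `html`, `bioc` (ground-truth `pubcorpus_bioc`),
#'   `abbrevs` (ground-truth `pubcorpus_abbrevset`), `tables` (ground-truth
#'   `pubcorpus_table` list for the inline tables), and `spec`.
#' @export
gen_article <- function(spec, lexicon = load_lexicon()) {
  stopifnot(inherits(spec, "pubcorpus_article_spec"))
  rz <- realize_article(spec, lexicon)
  dialect <- spec$dialect

  html <- c("<html><head><meta charset='utf-8'><title>Synthetic article</title></head><body>")
  truth_passages <- list()
  add_passage <- function(text, hp)
    truth_passages[[length(truth_passages) + 1L]] <<-
      list(text = text, heading_path = hp)

  table_html <- character(0)
  table_truth <- list()
  if (length(spec$tables)) {
    for (k in seq_along(spec$tables)) {
      gt <- gen_table(spec$tables[[k]])
      table_html <- c(table_html, gt$inline_fragment)
      table_truth <- c(table_truth, gt$truth)
    }
  }

  n <- length(rz$secs)
  for (i in seq_len(n)) {
    s <- rz$secs[[i]]
    html <- c(html, paste0("<h1 class='section-title-1'>", s$header_out,
                           "</h1>"))
    for (p in s$paras) {
      html <- c(html, wrap_para(p, dialect))
      add_passage(p, s$header_out)
    }
    for (sb in s$subs) {
      html <- c(html, paste0("<h2 class='section-title-2'>", sb$header,
                             "</h2>"),
                wrap_para(sb$text, dialect))
      add_passage(sb$text, c(s$header_out, sb$header))
    }
    if (i == n) {
      if (!is.null(rz$fig_text)) {
        html <- c(html, "<figure>",
                  wrap_para(rz$fig_text, "clean", class = "para"),
                  "</figure>")
        add_passage(rz$fig_text, s$header_out)
      }
      if (length(table_html)) html <- c(html, table_html)
    }
  }
  if (!is.null(rz$abbrev_text)) {
    html <- c(html, "<h1 class='section-title-1'>Abbreviations</h1>",
              wrap_para(rz$abbrev_text, dialect))
    # excluded from BioC ground truth by design
  }
  html <- c(html, "</body></html>")

  # ground-truth classifications per passage (deepest resolvable heading)
  sec_by_header <- setNames(rz$secs, vapply(rz$secs, `[[`, "", "header_out"))
  truth_bioc_passages <- list()
  offset <- 0L
  for (p in truth_passages) {
    main <- sec_by_header[[p$heading_path[1]]]
    terms_id <- main$truth_id
    if (length(p$heading_path) > 1L) {
      own <- match_lexical(p$heading_path[2], lexicon)
      if (!is.na(own)) terms_id <- own
    }
    infons <- list()
    for (k in seq_along(p$heading_path))
      infons[[paste0("section_title_", k)]] <- p$heading_path[k]
    for (k in seq_along(terms_id)) {
      infons[[paste0("iao_name_", k)]] <- iao_label(lexicon, terms_id[k])
      infons[[paste0("iao_id_", k)]] <- terms_id[k]
    }
    truth_bioc_passages[[length(truth_bioc_passages) + 1L]] <-
      list(offset = offset, infons = infons, text = p$text)
    offset <- offset + n_codepoints(p$text)
  }
  bioc <- structure(list(source = "pubcorpus", date = "19700101",
                         key = "pubcorpus_fulltext.key",
                         documents = list(list(id = spec$id,
                                               passages = truth_bioc_passages))),
                    class = "pubcorpus_bioc")

  # ground-truth abbreviation set, built directly from the plants
  aset <- list()
  for (a in spec$abbrevs) {
    if (a$placement %in% c("fulltext", "both")) {
      l <- a$fulltext_long %||% a$long
      aset[[a$short]][[l]] <- sort(unique(c(aset[[a$short]][[l]],
                                            "fulltext_bracket")))
    }
    if (a$placement %in% c("section", "both"))
      aset[[a$short]][[a$long]] <- sort(unique(c(aset[[a$short]][[a$long]],
                                                 "abbreviations_section")))
  }
  if (length(aset)) aset <- aset[order(names(aset))]

  list(html = paste(html, collapse = "\n"),
       bioc = bioc,
       abbrevs = structure(aset, class = "pubcorpus_abbrevset"),
       tables = table_truth,
       spec = spec)
}

#' Specify a synthetic table
#'
#' @param seed Integer seed determining cell values.
#' @param identifier Table number as a string (e.g. `"1"`).
#' @param col_types Character vector of declared column types
#'   (`"numerical"`, `"textual"`, `"mixed"`).
#' @param header_depth 1 or 2; depth 2 produces spanning top headers whose
#'   ground-truth column headers are pipe-joined.
#' @param n_rows Data rows (per section, for stub tables).
#' @param super_rows Character vector of section names rendered as
#'   full-width super rows (sections of `n_rows` rows each follow; an
#'   unnamed leading section is emitted when `lead_rows > 0`).
#' @param lead_rows Rows before the first super row.
#' @param stub Character vector of index-column section names; when set,
#'   the first column is a headerless stub column with one row-spanning
#'   cell per section (mutually exclusive with `super_rows`).
#' @param subtable_headers Character vector (textual) planting a sub-table:
#'   a mid-body header row over the declared columns followed by `n_rows`
#'   more data rows. Requires strictly more than half the columns
#'   numerical-or-mixed so the row is detected.
#' @param scientific Render one numerical column in superscript scientific
#'   notation (`a × 10<sup>-b</sup>`).
#' @param title,caption,footer Metadata strings.
#' @return A `table_spec` list.
#' @export
table_spec <- function(seed, identifier = "1",
                       col_types = c("textual", "numerical", "numerical"),
                       header_depth = 1, n_rows = 3, super_rows = NULL,
                       lead_rows = 0, stub = NULL, subtable_headers = NULL,
                       scientific = FALSE,
                       title = paste("Table", identifier,
                                     "Synthetic characteristics"),
                       caption = "Synthetic caption.",
                       footer = "Values are synthetic.") {
  stopifnot(header_depth %in% c(1, 2), n_rows >= 1,
            all(col_types %in% c("numerical", "textual", "mixed")))
  if (!is.null(stub) && !is.null(super_rows))
    pc_stop("stub and super_rows are mutually exclusive in one spec",
            class = "pubcorpus_fixture_error")
  if (!is.null(subtable_headers)) {
    if (length(subtable_headers) != length(col_types))
      pc_stop("subtable_headers must cover every column",
              class = "pubcorpus_fixture_error")
    if (sum(col_types != "textual") <= length(col_types) / 2)
      pc_stop("a planted sub-table needs >half non-textual columns to be ",
              "detectable", class = "pubcorpus_fixture_error")
  }
  structure(list(seed = seed, identifier = identifier,
                 col_types = col_types, header_depth = header_depth,
                 n_rows = n_rows, super_rows = super_rows,
                 lead_rows = lead_rows, stub = stub,
                 subtable_headers = subtable_headers,
                 scientific = scientific, title = title, caption = caption,
                 footer = footer),
            class = "pubcorpus_table_spec")
}

fixture_cell_value <- function(type, sci = FALSE) {
  if (type == "numerical") {
    if (sci) {
      coef <- sample(1:9, 1)
      expn <- sample(4:12, 1)
      list(html = paste0(coef, " × 10<sup>−", expn, "</sup>"),
           truth = coef * 10^(-expn))
    } else {
      v <- round(stats::runif(1, 0.01, 99.99), 2)
      list(html = format(v, nsmall = 2), truth = as.numeric(format(v, nsmall = 2)))
    }
  } else if (type == "textual") {
    w <- paste(sample(FIXTURE_VOCAB, 2), collapse = " ")
    list(html = w, truth = w)
  } else {
    v <- paste0("rs", sample(1000:9999, 1))
    list(html = v, truth = v)
  }
}

#' Generate a synthetic table with ground truth
#'
#' Emits both an inline fragment (a `table-wrap` container for embedding in
#' article HTML) and a standalone linked-table HTML file of the same grid;
#' both yield identical ground-truth TableDocuments.
#'
#' @param tspec A [table_spec()].
#' @return List with `inline_fragment`, `inline_html` (fragment wrapped in
#'   a full document), `linked_html`, and `truth` (list of
#'   `pubcorpus_table`, sub-tables as siblings).
#' @export
gen_table <- function(tspec) {
  stopifnot(inherits(tspec, "pubcorpus_table_spec"))
  with_seed(tspec$seed + 7L, {
    nc <- length(tspec$col_types)
    stub_mode <- !is.null(tspec$stub)
    sci_col <- if (tspec$scientific) which(tspec$col_types == "numerical")[1]
      else NA_integer_

    col_names <- paste0(toupper(substr(tspec$col_types, 1, 1)),
                        substr(tspec$col_types, 2, 100),
                        " ", seq_len(nc))
    # header rows
    thead <- character(0)
    if (tspec$header_depth == 1) {
      cells <- paste0("<th>", col_names, "</th>")
      if (stub_mode) cells <- c("<th></th>", cells)
      thead <- paste0("<tr>", paste(cells, collapse = ""), "</tr>")
      truth_headers <- col_names
    } else {
      # top header groups of two columns (last group absorbs remainder)
      n_groups <- max(1L, nc %/% 2L)
      sizes <- rep(2L, n_groups)
      sizes[n_groups] <- nc - 2L * (n_groups - 1L)
      group_names <- paste("Group", LETTERS[seq_len(n_groups)])
      top <- paste0("<th colspan='", sizes, "'>", group_names, "</th>")
      if (stub_mode) top <- c("<th rowspan='2'></th>", top)
      bottom <- paste0("<th>", col_names, "</th>")
      thead <- c(paste0("<tr>", paste(top, collapse = ""), "</tr>"),
                 paste0("<tr>", paste(bottom, collapse = ""), "</tr>"))
      truth_headers <- paste0(rep(group_names, sizes), "|", col_names)
    }

    render_data_row <- function(vals_html, stub_cell = NULL)
      paste0("<tr>", if (!is.null(stub_cell)) stub_cell else "",
             paste(paste0("<td>", vals_html, "</td>"), collapse = ""),
             "</tr>")
    make_row <- function() {
      cells <- lapply(seq_len(nc), function(c)
        fixture_cell_value(tspec$col_types[c],
                           sci = identical(c, sci_col)))
      list(html = vapply(cells, `[[`, "", "html"),
           truth = lapply(cells, `[[`, "truth"))
    }

    tbody <- character(0)
    # sections plan: list(name, n_rows); "" = unnamed leading section
    sections_plan <- list()
    if (stub_mode) {
      for (nm in tspec$stub)
        sections_plan[[length(sections_plan) + 1L]] <-
          list(name = nm, n = tspec$n_rows)
    } else if (!is.null(tspec$super_rows)) {
      if (tspec$lead_rows > 0)
        sections_plan[[length(sections_plan) + 1L]] <-
          list(name = "", n = tspec$lead_rows)
      for (nm in tspec$super_rows)
        sections_plan[[length(sections_plan) + 1L]] <-
          list(name = nm, n = tspec$n_rows)
    } else {
      sections_plan[[1]] <- list(name = "", n = tspec$n_rows)
    }

    truth_sections_parent <- list()
    for (sp in sections_plan) {
      rows_truth <- list()
      first <- TRUE
      for (k in seq_len(sp$n)) {
        rw <- make_row()
        if (stub_mode) {
          stub_cell <- if (first)
            paste0("<td rowspan='", sp$n, "'>", sp$name, "</td>") else NULL
          tbody <- c(tbody, render_data_row(rw$html, stub_cell))
        } else {
          if (first && nzchar(sp$name)) {
            span <- nc + if (stub_mode) 1L else 0L
            tbody <- c(tbody, paste0("<tr><td colspan='", span, "'>",
                                     sp$name, "</td></tr>"))
          }
          tbody <- c(tbody, render_data_row(rw$html))
        }
        rows_truth[[k]] <- rw$truth
        first <- FALSE
      }
      truth_sections_parent[[length(truth_sections_parent) + 1L]] <-
        list(name = sp$name, rows = rows_truth)
    }

    truth_sub <- NULL
    if (!is.null(tspec$subtable_headers)) {
      tbody <- c(tbody, render_data_row(tspec$subtable_headers,
                                        if (stub_mode) "<td></td>" else NULL))
      rows_truth <- list()
      for (k in seq_len(tspec$n_rows)) {
        rw <- make_row()
        tbody <- c(tbody, render_data_row(rw$html,
                                          if (stub_mode) "<td></td>" else NULL))
        rows_truth[[k]] <- rw$truth
      }
      truth_sub <- list(headers = tspec$subtable_headers,
                        rows = rows_truth)
    }

    table_el <- paste0(
      "<table class='data-table'><thead>",
      paste(thead, collapse = ""), "</thead><tbody>",
      paste(tbody, collapse = ""), "</tbody></table>")
    fragment <- paste0(
      "<div class='table-wrap'>",
      "<p class='table-title'>", tspec$title, "</p>",
      "<p class='table-caption'>", tspec$caption, "</p>",
      table_el,
      "<p class='table-footer'>", tspec$footer, "</p>",
      "</div>")
    inline_html <- paste0(
      "<html><head><meta charset='utf-8'></head><body>",
      "<h1 class='section-title-1'>Results</h1>",
      "<p class='para'>Synthetic results paragraph.</p>",
      fragment, "</body></html>")
    linked_html <- paste0(
      "<html><head><meta charset='utf-8'></head><body>",
      fragment, "</body></html>")

    # assemble ground-truth TableDocuments with cell identifiers
    meta <- list(title = tspec$title, caption = tspec$caption,
                 footer = tspec$footer)
    mk_doc <- function(id, headers, sections) {
      prefix <- paste0("T", id)
      ch <- data.frame(cell_id = paste0(prefix, ".C", seq_along(headers)),
                       text = headers, stringsAsFactors = FALSE)
      secs <- lapply(seq_along(sections), function(s) {
        sec <- sections[[s]]
        rws <- lapply(seq_along(sec$rows), function(k)
          lapply(seq_along(sec$rows[[k]]), function(ci)
            list(cell_id = paste0(prefix, ".S", s, ".R", k, ".C", ci),
                 value = sec$rows[[k]][[ci]])))
        list(name = sec$name, rows = rws)
      })
      structure(list(identifier = id, title = meta$title,
                     caption = meta$caption, footer = meta$footer,
                     column_headers = ch, sections = secs),
                class = "pubcorpus_table")
    }
    truth <- list(mk_doc(tspec$identifier, truth_headers,
                         truth_sections_parent))
    if (!is.null(truth_sub)) {
      sub_headers <- truth_sub$headers
      sub_secs <- list(list(name = "", rows = truth_sub$rows))
      if (stub_mode) {
        sub_headers <- c("", sub_headers)
        sub_secs[[1]]$rows <- lapply(sub_secs[[1]]$rows, function(r)
          c(list(""), r))
      }
      truth[[2]] <- mk_doc(paste0(tspec$identifier, "_1"), sub_headers,
                           sub_secs)
    }
    list(inline_fragment = fragment, inline_html = inline_html,
         linked_html = linked_html, truth = truth, spec = tspec)
  })
}

#' Packaged configuration for the fixture dialect
#' @return A `pubcorpus_config` matching [gen_article()] output.
#' @export
fixture_config <- function() {
  load_config(system.file("extdata", "configs", "fixture_dialect.json",
                          package = "pubcorpus"))
}

# Section-plan templates used by gen_corpus (headers are lexicon synonyms).
CORPUS_TEMPLATES <- list(
  c("Abstract", "Introduction", "Materials and Methods", "Results",
    "Discussion", "Conclusions"),
  c("Abstract", "Background", "Methods", "Results", "Discussion",
    "Funding"),
  c("Abstract", "Introduction", "Methods", "Results", "Discussion",
    "Acknowledgments"),
  c("Abstract", "Introduction", "Study Design", "Statistical Analysis",
    "Results", "Discussion"))

#' Generate a miniature corpus plus its exact expected section digraph
#'
#' Articles are drawn from a small pool of section-plan templates; a subset
#' receive a planted unmapped header (replacing one interior section, with
#' the replaced term recorded as ground truth) and a subset a planted typo
#' header. The expected digraph is computed by direct counting over the
#' ground-truth term chains (with the synthetic document-start node), which
#' is the training digraph for classifier tests.
#'
#' @param n Number of articles (>= 1).
#' @param seed Integer seed.
#' @param lexicon A `pubcorpus_lexicon`.
#' @return List with `articles` (each a [gen_article()] result), `digraph`
#'   (expected `pubcorpus_digraph`), and `plants` (data.frame `article`,
#'   `position`, `header`, `truth_id` for the unmapped plants).
#' @export
gen_corpus <- function(n, seed, lexicon = load_lexicon()) {
  stopifnot(n >= 1)
  specs <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      tpl <- CORPUS_TEMPLATES[[sample(length(CORPUS_TEMPLATES), 1)]]
      secs <- lapply(tpl, function(h) list(header = h, mode = "lexical"))
      kind <- sample(c("plain", "typo", "unmapped"), 1,
                     prob = c(0.5, 0.2, 0.3))
      if (kind == "typo") {
        # perturb a header with a long synonym (stays above threshold)
        longish <- which(nchar(normalize_header(tpl)) >= 8)
        j <- longish[sample(length(longish), 1)]
        secs[[j]]$mode <- "typo"
      } else if (kind == "unmapped") {
        j <- sample(2:(length(tpl) - 1L), 1)
        truth <- match_lexical(tpl[j], lexicon)
        secs[[j]] <- list(header = paste0("Zorble ", sample(1000:9999, 1)),
                          mode = "unmapped", truth = truth)
      }
      article_spec(seed = seed * 1000L + i, sections = secs,
                   id = sprintf("SYN%04d", i))
    })
  })
  articles <- lapply(specs, gen_article, lexicon = lexicon)

  # expected digraph: direct counting over ground-truth term chains
  g <- empty_digraph()
  plants <- data.frame(article = integer(0), position = integer(0),
                       header = character(0), truth_id = character(0),
                       stringsAsFactors = FALSE)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    labels <- vapply(sp$sections, function(s) {
      id <- if (s$mode == "unmapped") s$truth
        else match_lexical(s$header, lexicon)
      iao_label(lexicon, id)
    }, "")
    labels <- labels[c(TRUE, labels[-1] != labels[-length(labels)])]
    chain <- c(START_NODE, labels)
    for (k in chain) {
      j <- match(k, g$nodes$label)
      if (is.na(j)) g$nodes <- rbind(g$nodes, data.frame(
        label = k, weight = 1L, stringsAsFactors = FALSE))
      else g$nodes$weight[j] <- g$nodes$weight[j] + 1L
    }
    for (k in seq_len(length(chain) - 1L)) {
      j <- which(g$edges$from == chain[k] & g$edges$to == chain[k + 1L])
      if (length(j)) g$edges$weight[j] <- g$edges$weight[j] + 1L
      else g$edges <- rbind(g$edges, data.frame(
        from = chain[k], to = chain[k + 1L], weight = 1L,
        stringsAsFactors = FALSE))
    }
    for (p in seq_along(sp$sections)) {
      s <- sp$sections[[p]]
      if (s$mode == "unmapped")
        plants <- rbind(plants, data.frame(
          article = i, position = p, header = s$header,
          truth_id = s$truth, stringsAsFactors = FALSE))
    }
  }
  list(articles = articles, digraph = g, plants = plants)
}

#' Write a fixture tree (html/ and truth/) to a directory
#'
#' @param n Number of articles.
#' @param seed Integer seed.
#' @param dir Target directory (created if needed).
#' @return The manifest of written files, invisibly.
#' @export
write_fixture_tree <- function(n, seed, dir) {
  corpus <- gen_corpus(n, seed)
  html_dir <- file.path(dir, "html")
  truth_dir <- file.path(dir, "truth")
  dir.create(html_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(truth_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (a in corpus$articles) {
    stem <- a$spec$id
    hf <- file.path(html_dir, paste0(stem, ".html"))
    writeLines(a$html, hf, useBytes = TRUE)
    bf <- file.path(truth_dir, paste0(stem, "_bioc.json"))
    write_bioc(a$bioc, bf)
    files <- c(files, hf, bf)
  }
  gf <- file.path(truth_dir, "digraph.json")
  write_digraph(corpus$digraph, gf)
  invisible(c(files, gf))
}
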