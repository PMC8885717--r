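grid_from_html <- function(tbl_html) {
  doc <- xml2::read_html(tbl_html)
  extract_grid(xml2::xml_find_first(doc, "//table"))
}

test_that("parse_cell applies the number/string rules", {
  expect_identical(parse_cell("5 × 10<sup>−8</sup>"), 5e-8)
  expect_identical(parse_cell("1.3E-4"), 1.3e-4)
  expect_identical(parse_cell("true"), "true")
  expect_identical(parse_cell("false"), "false")
  expect_identical(parse_cell("n = 10<sup>3</sup>"), "n = 10 <sup>3</sup>")
  expect_identical(parse_cell("−0.5"), -0.5)       # unicode minus
  expect_identical(parse_cell("–12"), -12)         # en dash as minus
  expect_identical(parse_cell("1,234"), "1,234")   # comma: not a number
  expect_identical(parse_cell("<b>42</b>"), 42)
  expect_identical(parse_cell(""), "")
  expect_identical(parse_cell("rs123"), "rs123")
})

test_that("numeric parsing agrees with a decimal oracle on generated strings", {
  set.seed(501)
  for (k in 1:1000) {
    coef <- round(stats::runif(1, 0.1, 99), sample(0:3, 1))
    expn <- sample(-12:12, 1)
    style <- sample(1:4, 1)
    minus <- if (expn < 0) sample(c("-", "−", "–"), 1) else
      sample(c("", "+"), 1)
    etxt <- paste0(minus, abs(expn))
    raw <- switch(style,
      paste0(coef, " × 10<sup>", etxt, "</sup>"),
      paste0(coef, " x 10<sup>", etxt, "</sup>"),
      paste0(coef, "E", etxt),
      as.character(coef))
    want <- if (style == 4) coef else coef * 10^expn
    expect_equal(parse_cell(raw), want, tolerance = 1e-12)
  }
})

test_that("span expansion replicates source cells into every covered slot", {
  g <- grid_from_html(
    "<table><tr><th colspan='2'>Cases</th><th rowspan='2'>P</th></tr>
     <tr><th>n</th><th>%</th></tr>
     <tr><td>1</td><td>2</td><td>3</td></tr></table>")
  expect_identical(dim(g$occ), c(3L, 3L))
  expect_identical(g$occ[1, 1], g$occ[1, 2])       # colspan replication
  expect_identical(g$occ[1, 3], g$occ[2, 3])       # rowspan replication
  expect_true(all(g$occ > 0L))
})

test_that("multi-row headers are pipe-joined and span text replicated per column", {
  g <- grid_from_html(
    "<table><tr><th>Allele</th></tr><tr><th>frequency</th></tr>
     <tr><td>0.1</td></tr></table>")
  expect_identical(resolve_headers(g)$headers, "Allele|frequency")

  g2 <- grid_from_html(
    "<table><tr><th colspan='2'>Cases</th></tr>
     <tr><th>n</th><th>%</th></tr>
     <tr><td>5</td><td>50</td></tr></table>")
  expect_identical(resolve_headers(g2)$headers, c("Cases|n", "Cases|%"))

  g3 <- grid_from_html(
    "<table><tr><th>A</th><th>B</th></tr><tr><td>1</td><td>2</td></tr></table>")
  expect_identical(resolve_headers(g3)$headers, c("A", "B"))
})

test_that("tables without header markup fall back to the first row", {
  g <- grid_from_html(
    "<table><tr><td>A</td><td>B</td></tr><tr><td>1</td><td>2</td></tr></table>")
  rh <- resolve_headers(g)
  expect_identical(rh$headers, c("A", "B"))
  expect_identical(rh$body_rows, 2L)
})

test_that("super rows divide sections; leading rows form an unnamed section", {
  g <- grid_from_html(
    "<table><tr><th>A</th><th>B</th></tr>
     <tr><td colspan='2'>Men</td></tr><tr><td>1</td><td>2</td></tr>
     <tr><td colspan='2'>Women</td></tr><tr><td>3</td><td>4</td></tr></table>")
  rh <- resolve_headers(g)
  seg <- segment_sections(g, rh$body_rows, rh$headers)
  expect_identical(vapply(seg$sections, `[[`, "", "name"),
                   c("Men", "Women"))
  g2 <- grid_from_html(
    "<table><tr><th>A</th><th>B</th></tr><tr><td>1</td><td>2</td></tr></table>")
  rh2 <- resolve_headers(g2)
  seg2 <- segment_sections(g2, rh2$body_rows, rh2$headers)
  expect_identical(vapply(seg2$sections, `[[`, "", "name"), "")
})

test_that("a headerless first column with row-spanning cells acts as a stub", {
  # 4x3 grid: stub column with "Cohort A" spanning rows 1-2, "Cohort B" rows 3-4
  g <- grid_from_html(
    "<table><tr><th></th><th>X</th><th>Y</th></tr>
     <tr><td rowspan='2'>Cohort A</td><td>1</td><td>2</td></tr>
     <tr><td>3</td><td>4</td></tr>
     <tr><td rowspan='2'>Cohort B</td><td>5</td><td>6</td></tr>
     <tr><td>7</td><td>8</td></tr></table>")
  rh <- resolve_headers(g)
  seg <- segment_sections(g, rh$body_rows, rh$headers)
  expect_true(seg$drop_first_col)
  expect_identical(seg$headers, c("X", "Y"))
  expect_identical(vapply(seg$sections, `[[`, "", "name"),
                   c("Cohort A", "Cohort B"))
  expect_identical(lengths(lapply(seg$sections, `[[`, "rows")),
                   c(2L, 2L))
})

test_that("column types follow the majority rule with documented tie defaults", {
  g <- grid_from_html(paste0(
    "<table><tr><th>A</th><th>B</th><th>C</th></tr>",
    "<tr><td>1.2</td><td>rs123</td><td></td></tr>",
    "<tr><td>0.4</td><td>rs456</td><td></td></tr>",
    "<tr><td>n/a</td><td>rs789</td><td></td></tr></table>"))
  types <- classify_columns(g, 2:4)
  expect_identical(types, c("numerical", "mixed", "textual"))
})

test_that("the sub-table rule is strictly more than half", {
  mk <- function(midrow) grid_from_html(paste0(
    "<table><tr><th>A</th><th>B</th><th>C</th><th>D</th></tr>",
    "<tr><td>1</td><td>2</td><td>3</td><td>4</td></tr>",
    "<tr><td>5</td><td>6</td><td>7</td><td>8</td></tr>",
    midrow,
    "<tr><td>9</td><td>1</td><td>2</td><td>3</td></tr></table>"))
  # 4 of 4 textual cells mismatch the numeric columns: split
  g_split <- mk("<tr><td>OR</td><td>CI</td><td>P</td><td>Beta</td></tr>")
  docs <- analyze_grid(g_split, "1")
  expect_identical(vapply(docs, `[[`, "", "identifier"), c("1", "1_1"))
  expect_identical(docs[[2]]$column_headers$text, c("OR", "CI", "P", "Beta"))
  expect_identical(docs[[2]]$title, docs[[1]]$title)
  # exactly half (2 of 4) does NOT split
  g_half <- mk("<tr><td>OR</td><td>CI</td><td>7</td><td>8</td></tr>")
  expect_length(analyze_grid(g_half, "1"), 1L)
  # 3 of 4 does
  g_three <- mk("<tr><td>OR</td><td>CI</td><td>P</td><td>8</td></tr>")
  expect_length(analyze_grid(g_three, "1"), 2L)
})

test_that("layout tables are excluded and identifiers parsed from titles", {
  cfg <- fixture_config()
  html <- paste0(
    "<html><body>",
    "<div class='table-wrap'><p class='table-title'>Table 3 Clinical characteristics</p>",
    "<table class='data-table'><tr><th>A</th></tr><tr><td>1</td></tr></table></div>",
    "<table class='layout'><tr><td>nav</td></tr></table>",
    "<div class='table-wrap'><table class='data-table'>",
    "<tr><th>B</th></tr><tr><td>2</td></tr></table></div>",
    "</body></html>")
  tt <- locate_tables(html, cfg, "inline")
  expect_length(tt, 2L)
  expect_identical(tt[[1]]$identifier, "3")
  expect_identical(tt[[2]]$identifier, "2")  # positional fallback
  expect_warning(locate_tables("<html><body></body></html>", cfg, "linked"),
                 class = "pubcorpus_no_tables")
})

test_that("row arity always equals the block's header count", {
  for (seed in 1:6) {
    specs <- list(table_spec(seed), table_spec(seed, header_depth = 2),
                  table_spec(seed, super_rows = "S", lead_rows = 1),
                  table_spec(seed, stub = c("A", "B")))
    for (ts in specs) {
      g <- gen_table(ts)
      docs <- process_tables(g$linked_html, fixture_config(), "linked")
      for (d in docs) {
        arity <- nrow(d$column_headers)
        for (s in d$sections) for (row in s$rows)
          expect_length(row, arity)
      }
    }
  }
})

test_that("cell identifiers are unique and follow the documented scheme", {
  g <- gen_table(table_spec(9, super_rows = c("M", "W")))
  docs <- process_tables(g$linked_html, fixture_config(), "linked")
  d <- docs[[1]]
  expect_identical(d$column_headers$cell_id[1], "T1.C1")
  expect_identical(d$sections[[1]]$rows[[1]][[1]]$cell_id, "T1.S1.R1.C1")
  all_ids <- c(d$column_headers$cell_id,
               unlist(lapply(d$sections, function(s)
                 lapply(s$rows, function(r)
                   vapply(r, `[[`, "", "cell_id")))))
  expect_false(any(duplicated(all_ids)))
})

test_that("table JSON round-trips, validates, and rejects duplicate identifiers", {
  g <- gen_table(table_spec(13, header_depth = 2,
                            col_types = c("textual", "numerical",
                                          "numerical", "mixed"),
                            subtable_headers = NULL))
  path <- withr::local_tempfile(fileext = ".json")
  build_table_json(g$truth, path, doc_id = "d")
  expect_silent(validate_table_json(path))
  back <- read_table_json(path)
  expect_identical(lapply(back$tables, unclass), lapply(g$truth, unclass))
  # metadata passages carry the three section-type labels
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  labs <- vapply(obj$documents[[1]]$tables[[1]]$metadata, `[[`, "",
                 "section_type")
  expect_identical(labs, c("table_title", "table_caption", "table_footer"))
  # empty table list is valid
  build_table_json(list(), path, doc_id = "d")
  expect_silent(validate_table_json(path))
  # duplicate identifiers error
  expect_error(build_table_json(c(g$truth[1], g$truth[1]), path),
               class = "pubcorpus_table_error")
})

test_that("every non-empty body cell is conserved exactly once in the output", {
  for (seed in c(21, 22)) {
    for (ts in list(table_spec(seed),
                    table_spec(seed, super_rows = c("M", "W")),
                    table_spec(seed,
                               col_types = c("numerical", "numerical",
                                             "numerical", "mixed"),
                               subtable_headers = c("OR", "CI", "P", "B")))) {
      g <- gen_table(ts)
      docs <- process_tables(g$linked_html, fixture_config(), "linked")
      # independent source inventory: all tbody cell texts from the HTML
      doc <- xml2::read_html(g$linked_html)
      tds <- xml2::xml_find_all(doc, "//tbody//td")
      src <- vapply(tds, function(td) strip_markup(as.character(td)), "")
      src <- src[nzchar(src)]
      # emitted inventory: data values + section names + sub-table headers
      emitted <- character(0)
      for (k in seq_along(docs)) {
        d <- docs[[k]]
        for (s in d$sections) {
          if (nzchar(s$name)) emitted <- c(emitted, s$name)
          for (row in s$rows)
            for (cell in row) {
              v <- cell$value
              v <- if (is.numeric(v)) strip_markup(format(v, trim = TRUE))
                else gsub(" ?</?sup>", "", v)
              if (nzchar(v)) emitted <- c(emitted, v)
            }
        }
        if (k > 1L) emitted <- c(emitted, d$column_headers$text)
      }
      norm_num <- function(x) vapply(x, function(v) {
        n <- suppressWarnings(as.numeric(v))
        if (!is.na(n)) format(n, trim = TRUE) else v
      }, "", USE.NAMES = FALSE)
      expect_identical(sort(norm_num(emitted)), sort(norm_num(src)),
                       info = paste("seed", seed))
    }
  }
})
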