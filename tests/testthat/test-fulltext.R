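simple_cfg <- function() {
  as_config(list(selectors = list(
    heading = list(list(element = "h1"), list(element = "h2")),
    paragraph = list(list(element = "p")))))
}

test_that("strip_markup removes tags, keeps anchors, decodes entities, is idempotent", {
  expect_identical(strip_markup("see <a href='#f1'>Figure 1</a>"),
                   "see Figure 1")
  expect_identical(strip_markup("<i>P</i>-value"), "P-value")
  expect_identical(strip_markup("10<sup>3</sup> samples"), "103 samples")
  expect_identical(strip_markup("a &amp; b &#946;"), "a & b β")
  expect_identical(strip_markup("  many    spaces\t\nhere "),
                   "many spaces here")
  expect_identical(strip_markup(""), "")
  cases <- c("plain text", "x < y is fine?", "<b>bold <i>nest</i></b>",
             "a&nbsp;b", "see <a href='x'>link</a> end")
  for (x in cases)
    expect_identical(strip_markup(strip_markup(x)), strip_markup(x))
})

test_that("headings delineate passages and sub-headings extend the path", {
  html <- "<html><body>
    <h1>Abstract</h1><p>First passage.</p>
    <h1>Introduction</h1><p>Second passage.</p>
    <h2>Motivation</h2><p>Third passage.</p>
    <h1>Methods</h1><p>Fourth passage.</p></body></html>"
  m <- parse_article(html, simple_cfg(), "d1")
  expect_length(m$passages, 4L)
  expect_identical(m$passages[[1]]$heading_path, "Abstract")
  expect_identical(m$passages[[2]]$heading_path, "Introduction")
  expect_identical(m$passages[[3]]$heading_path,
                   c("Introduction", "Motivation"))
  expect_identical(m$passages[[4]]$heading_path, "Methods")
})

test_that("zero selector matches yield an empty model with a warning", {
  cfg <- as_config(list(selectors = list(
    heading = list(list(element = "h6")),
    paragraph = list(list(element = "blockquote")))))
  expect_warning(m <- parse_article("<html><body><p>hi</p></body></html>",
                                    cfg, "d"),
                 class = "pubcorpus_empty_article")
  expect_length(m$passages, 0L)
})

test_that("malformed HTML is recovered without losing paragraph text", {
  html <- "<html><body><h1>Results</h1>
    <p>First unclosed
    <p>Second <span>wrapped</body>"
  m <- parse_article(html, simple_cfg(), "d")
  expect_length(m$passages, 2L)
  expect_identical(m$passages[[1]]$text, "First unclosed")
  expect_identical(m$passages[[2]]$text, "Second wrapped")
})

test_that("document ids come from filename stems with PMC patterns verbatim", {
  expect_identical(document_id("/x/y/PMC1234567.html"), "PMC1234567")
  expect_identical(document_id("study_PMC123_final.html"), "PMC123")
  expect_identical(document_id("my_article.html"), "my_article")
})

test_that("build_bioc computes cumulative code-point offsets and infons", {
  m <- structure(list(document_id = "d", passages = list(
    list(text = strrep("a", 100), heading_path = "Intro",
         is_caption = FALSE),
    list(text = strrep("β", 50), heading_path = "Intro",
         is_caption = FALSE))), class = "pubcorpus_article")
  cls <- list(
    data.frame(iao_name = "introduction section", iao_id = "IAO:0000316",
               stringsAsFactors = FALSE),
    data.frame(iao_name = "introduction section", iao_id = "IAO:0000316",
               stringsAsFactors = FALSE))
  b <- build_bioc(m, cls)
  p <- b$documents[[1]]$passages
  expect_identical(p[[1]]$offset, 0L)
  expect_identical(p[[2]]$offset, 100L)  # code points, not bytes
  expect_identical(p[[1]]$infons$section_title_1, "Intro")
  expect_identical(p[[1]]$infons$iao_id_1, "IAO:0000316")
  expect_silent(validate_bioc(b))
})

test_that("methods-section passages carry the expected IAO infons end to end", {
  html <- "<html><body><h1>Materials and Methods</h1><p>We did things.</p></body></html>"
  m <- parse_article(html, simple_cfg(), "d")
  cls <- classify_sections(m, load_lexicon())
  b <- build_bioc(m, cls)
  infons <- b$documents[[1]]$passages[[1]]$infons
  expect_identical(infons$iao_name_1, "methods section")
  expect_identical(infons$iao_id_1, "IAO:0000317")
})

test_that("abbreviations-section passages are excluded from BioC output", {
  html <- paste0("<html><body><h1>Results</h1><p>Stuff happened.</p>",
                 "<h1>Abbreviations</h1><p>GW: genome wide</p>",
                 "</body></html>")
  m <- parse_article(html, simple_cfg(), "d")
  cls <- classify_sections(m, load_lexicon())
  b <- build_bioc(m, cls)
  texts <- vapply(b$documents[[1]]$passages, `[[`, "", "text")
  expect_length(texts, 1L)
  expect_false(any(grepl("genome wide", texts)))
})

test_that("misaligned classification lists are an internal error", {
  m <- structure(list(document_id = "d", passages = list(
    list(text = "x", heading_path = "A", is_caption = FALSE))),
    class = "pubcorpus_article")
  expect_error(build_bioc(m, list()), class = "pubcorpus_internal_error")
})

test_that("BioC JSON round-trips exactly and validates, including empty models", {
  g <- gen_article(demo_article_spec(11))
  path <- withr::local_tempfile(fileext = ".json")
  write_bioc(g$bioc, path)
  expect_silent(validate_bioc(read_bioc(path)))
  expect_identical(unclass(read_bioc(path)), unclass(g$bioc))

  empty <- structure(list(document_id = "e", passages = list()),
                     class = "pubcorpus_article")
  b <- build_bioc(empty, list())
  write_bioc(b, path)
  expect_silent(validate_bioc(read_bioc(path)))
  expect_length(read_bioc(path)$documents[[1]]$passages, 0L)
})

test_that("offsets increase by exactly the preceding passage length", {
  g <- gen_article(demo_article_spec(12))
  p <- g$bioc$documents[[1]]$passages
  for (i in seq_len(length(p) - 1L))
    expect_identical(p[[i + 1L]]$offset,
                     p[[i]]$offset + nchar(p[[i]]$text, type = "chars"))
})
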