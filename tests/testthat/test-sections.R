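lex <- load_lexicon()

test_that("normalization lowercases, strips non-alphanumerics, is idempotent", {
  expect_identical(normalize_header("Materials and Methods"),
                   "materialsandmethods")
  expect_identical(normalize_header(""), "")
  expect_identical(normalize_header("Conflict-of-Interest!"),
                   "conflictofinterest")
  for (x in c("A  B", "Déjà-vu 2", "x_y.z"))
    expect_identical(normalize_header(normalize_header(x)),
                     normalize_header(x))
})

test_that("lexical matching resolves labels and synonyms, none otherwise", {
  expect_identical(match_lexical("abstract", lex), "IAO:0000315")
  expect_identical(match_lexical("Experimental Procedures", lex),
                   "IAO:0000317")
  expect_identical(match_lexical("Background", lex), "IAO:0000316")
  expect_identical(match_lexical("Zorbleflux", lex), NA_character_)
})

test_that("every packaged synonym maps to exactly one entry", {
  expect_false(anyDuplicated(lex$synonyms$norm) > 0L &&
    any(tapply(lex$synonyms$iao_id, lex$synonyms$norm,
               function(x) length(unique(x))) > 1L))
  # and the loader rejects a lexicon violating this
  bad <- data.frame(iao_id = c("IAO:1", "IAO:2"), label = c("a", "b"),
                    synonym = c("same term", "same-term"),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon_tsv(bad, path)
  expect_error(load_lexicon(path), class = "pubcorpus_lexicon_error")
})

test_that("the typo 'experemintal section' fuzzy-maps to the methods section", {
  fz <- match_fuzzy("experemintal section", lex)
  expect_gte(nrow(fz), 1L)
  expect_identical(fz$iao_id[1], "IAO:0000317")
  expect_identical(fz$iao_name[1], "methods section")
  expect_gte(fz$score[1], 0.8)
  # frozen oracle value: LCS("experemintalsection","experimentalsection")=17
  expect_equal(fz$score[1], 2 * 17 / 38, tolerance = 1e-12)
})

test_that("an exact synonym scores 1.0 and lexical matches preempt fuzzy", {
  fz <- match_fuzzy("statistical analysis", lex)
  expect_identical(fz$iao_id[1], "IAO:0000644")
  expect_equal(fz$score[1], 1.0)
  res <- pubcorpus:::resolve_header("statistical analysis", lex)
  expect_identical(res$method, "lexical")
})

test_that("fuzzy scores equal the brute-force LCS-ratio oracle", {
  set.seed(401)
  syn <- data.frame(
    iao_id = sprintf("IAO:%07d", 1:40), label = sprintf("label%02d", 1:40),
    synonym = vapply(1:40, function(i)
      rand_string(20, letters[1:5]), ""), stringsAsFactors = FALSE)
  syn <- syn[nzchar(normalize_header(syn$synonym)), ]
  syn <- syn[!duplicated(normalize_header(syn$synonym)), ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon_tsv(syn, path)
  tiny <- load_lexicon(path)
  for (k in 1:25) {
    header <- rand_string(20, letters[1:5])
    thr <- 0.3
    fz <- match_fuzzy(header, tiny, fuzzy_config(thr))
    h <- normalize_header(header)
    oracle_best <- vapply(tiny$entries$iao_id, function(id) {
      s <- tiny$synonyms$norm[tiny$synonyms$iao_id == id]
      max(vapply(s, function(x) ratio_oracle(h, x), 0))
    }, 0)
    # completeness: exactly the entries at/above threshold are returned
    expect_setequal(fz$iao_id,
                    tiny$entries$iao_id[oracle_best >= thr])
    # score equality and descending order
    for (i in seq_len(nrow(fz)))
      expect_equal(fz$score[i], unname(oracle_best[fz$iao_id[i]]),
                   tolerance = 1e-12)
    expect_false(is.unsorted(rev(fz$score)))
  }
})

test_that("DPGs are linear chains with consecutive duplicates collapsed", {
  d <- build_dpg(c("abstract", "introduction", "materials and methods"), lex)
  expect_length(d$nodes, 3L)  # 3 nodes, hence 2 directed edges
  d2 <- build_dpg(c("intro", "Intro!", "results"), lex)
  expect_length(d2$nodes, 2L)  # duplicate headers collapse, no self-edge
  expect_length(build_dpg(character(0), lex)$nodes, 0L)
  # property: no two consecutive nodes share a normalized header
  set.seed(77)
  pool <- c("Abstract", "Introduction", "Methods", "Results", "results",
            "Discussion", "Wibble")
  for (k in 1:25) {
    hs <- sample(pool, sample(0:12, 1), replace = TRUE)
    d <- build_dpg(hs, lex)
    norms <- vapply(d$nodes, `[[`, "", "norm")
    if (length(norms) > 1L)
      expect_true(all(norms[-1] != norms[-length(norms)]))
    expect_lte(length(norms), length(hs))
  }
})

test_that("digraph merging counts publications and conserves totals", {
  d <- build_dpg(c("abstract", "introduction", "methods"), lex)
  g <- accumulate_digraph(empty_digraph(), d)
  g <- accumulate_digraph(g, d)
  expect_true(all(g$nodes$weight == 2L))
  expect_true(all(g$edges$weight == 2L))
  # two DPGs sharing only "introduction"
  g2 <- accumulate_digraph(empty_digraph(),
                           build_dpg(c("abstract", "introduction"), lex))
  g2 <- accumulate_digraph(g2, build_dpg(c("introduction", "results"), lex))
  w <- setNames(g2$nodes$weight, g2$nodes$label)
  expect_identical(unname(w[["introduction section"]]), 2L)
  expect_true(all(w[setdiff(names(w),
                            c("introduction section",
                              pubcorpus:::START_NODE))] == 1L))
  # merging an empty DPG changes nothing
  expect_identical(accumulate_digraph(g, build_dpg(character(0), lex)), g)
  # conservation: per merge, node-weight gain = #nodes+1 (start), edges = #nodes
  g3 <- accumulate_digraph(g, d)
  expect_identical(sum(g3$nodes$weight) - sum(g$nodes$weight),
                   length(d$nodes) + 1L)
  expect_identical(sum(g3$edges$weight) - sum(g$edges$weight),
                   length(d$nodes))
})

test_that("digraph JSON serialization round-trips exactly", {
  corpus <- gen_corpus(8, 99)
  path <- withr::local_tempfile(fileext = ".json")
  write_digraph(corpus$digraph, path)
  g2 <- read_digraph(path)
  expect_identical(g2$nodes, corpus$digraph$nodes)
  expect_identical(g2$edges, corpus$digraph$edges)
})

test_that("unmapped headers take the heaviest anchor-bounded digraph path", {
  # digraph: introduction -> methods -> results (heavy)
  #          introduction -> discussion -> results (light)
  g <- empty_digraph()
  heavy <- build_dpg(c("introduction", "methods", "results"), lex)
  light <- build_dpg(c("introduction", "discussion", "results"), lex)
  for (i in 1:10) g <- accumulate_digraph(g, heavy)
  for (i in 1:2) g <- accumulate_digraph(g, light)
  d <- build_dpg(c("introduction", "Cohort assembly xyz", "results"), lex)
  expect_identical(vapply(d$nodes, `[[`, "", "status")[2], "unmapped")
  p <- predict_unmapped(d, g, lex)
  expect_identical(p$nodes[[2]]$status, "digraph")
  expect_identical(p$nodes[[2]]$terms$iao_id, "IAO:0000317")
  # fully mapped DPGs come back unchanged
  expect_identical(predict_unmapped(heavy, g, lex), heavy)
  # ties retain all tied terms
  g_tie <- empty_digraph()
  for (i in 1:3) g_tie <- accumulate_digraph(g_tie, heavy)
  for (i in 1:3) g_tie <- accumulate_digraph(g_tie, light)
  p2 <- predict_unmapped(d, g_tie, lex)
  expect_setequal(p2$nodes[[2]]$terms$iao_id,
                  c("IAO:0000317", "IAO:0000319"))
  # no anchors at all: unchanged with a warning
  d3 <- build_dpg(c("Wibble one", "Wobble two"), lex)
  expect_warning(p3 <- predict_unmapped(d3, g, lex),
                 class = "pubcorpus_no_anchor")
  expect_true(all(vapply(p3$nodes, `[[`, "", "status") == "unmapped"))
})

test_that("leading unmapped headers are anchored on the document-start node", {
  g <- empty_digraph()
  for (i in 1:5)
    g <- accumulate_digraph(g, build_dpg(c("abstract", "results"), lex))
  d <- build_dpg(c("Prelude xyz", "results"), lex)
  p <- predict_unmapped(d, g, lex)
  expect_identical(p$nodes[[1]]$terms$iao_name, "abstract")
})

test_that("the classification cascade is lexical, then fuzzy, then digraph", {
  cfg <- as_config(list(selectors = list(
    heading = list(list(element = "h1"), list(element = "h2")),
    paragraph = list(list(element = "p")))))
  corpus <- gen_corpus(30, 55)
  html <- paste0("<html><body>",
                 "<h1>Abstract</h1><p>A.</p>",
                 "<h1>Background</h1><p>B.</p>",
                 "<h1>experemintal section</h1><p>C.</p>",
                 "<h1>Unknowable stanza</h1><p>D.</p>",
                 "<h1>Discussion</h1><p>E.</p>",
                 "</body></html>")
  m <- parse_article(html, cfg, "d")
  cls <- classify_sections(m, lex, corpus$digraph)
  expect_identical(cls[[1]]$iao_id, "IAO:0000315")
  expect_identical(cls[[2]]$iao_id, "IAO:0000316")   # Background -> introduction
  expect_identical(cls[[3]]$iao_id, "IAO:0000317")   # typo via fuzzy
  expect_identical(cls[[5]]$iao_id, "IAO:0000319")
  # the unmapped header got a digraph prediction bounded by its anchors
  expect_gte(nrow(cls[[4]]), 1L)
  expect_true(all(cls[[4]]$iao_id %in% lex$entries$iao_id))
})

test_that("sub-headers classify on their own and only then inherit", {
  cfg <- as_config(list(selectors = list(
    heading = list(list(element = "h1"), list(element = "h2")),
    paragraph = list(list(element = "p")))))
  html <- paste0("<html><body><h1>Materials and Methods</h1><p>A.</p>",
                 "<h2>Statistical Analysis</h2><p>B.</p>",
                 "<h2>Qqzx vvwk</h2><p>C.</p></body></html>")
  m <- parse_article(html, cfg, "d")
  cls <- classify_sections(m, lex)
  expect_identical(cls[[1]]$iao_id, "IAO:0000317")
  expect_identical(cls[[2]]$iao_id, "IAO:0000644")  # own classification
  expect_identical(cls[[3]]$iao_id, "IAO:0000317")  # inherited from main
})
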