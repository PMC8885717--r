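# Independent brute-force oracles used by the property suites.
# These are deliberately written against the textbook definitions only and
# never call into the package's own LCS kernel.

# Quadratic dynamic-programming LCS length over code points.
lcs_oracle <- function(a, b) {
  A <- utf8ToInt(enc2utf8(a))
  B <- utf8ToInt(enc2utf8(b))
  n <- length(A); m <- length(B)
  if (n == 0L || m == 0L) return(0L)
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    for (j in seq_len(m)) {
      cur[j + 1L] <- if (A[i] == B[j]) prev[j] + 1L
        else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

# SequenceMatcher-style similarity ratio on raw strings.
ratio_oracle <- function(a, b) {
  na <- nchar(a, type = "chars"); nb <- nchar(b, type = "chars")
  if (na + nb == 0L) return(1)
  2 * lcs_oracle(a, b) / (na + nb)
}

rand_string <- function(max_len = 30L, alphabet = c(letters[1:6], " ")) {
  n <- sample(0:max_len, 1L)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Fixture article spec pool exercising sub-headers, typos, abbreviation
# placements and encoding quirks.
demo_article_spec <- function(seed, placement = "both") {
  article_spec(
    seed = seed,
    sections = list(
      list(header = "Abstract"),
      list(header = "Introduction"),
      list(header = "Materials and Methods",
           subs = c("Statistical Analysis")),
      list(header = "Results"),
      list(header = "Discussion")),
    abbrevs = list(
      list(short = "GWAS", long = "genome-wide association study",
           placement = placement),
      list(short = "RP", long = "reverse phase", placement = "both",
           fulltext_long = "reversed phase")),
    id = paste0("SYN", seed))
}

write_lexicon_tsv <- function(entries, path) {
  # entries: data.frame(iao_id, label, synonym)
  utils::write.table(entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}
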