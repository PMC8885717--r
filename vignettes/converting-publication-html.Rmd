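---
title: "Standardizing publication HTML: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing publication HTML: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pubcorpus)
```

## The problem

Full-text biomedical articles are distributed as HTML in as many dialects
as there are publishers. Before any text-mining step — named-entity
recognition, relation extraction, corpus statistics — the text has to be
standardized: sections identified and named consistently, tables turned
from visual grids into addressable data, abbreviations resolved. pubcorpus
converts one article's HTML (plus any linked one-table-per-file HTML) into
BioC JSON, a structured table JSON, and an abbreviations JSON, driven by a
per-publisher configuration file.

This vignette records the model behind each stage, the parameters that
matter, and the design decisions taken where more than one reasonable
choice existed.

## Source configurations

A configuration names the HTML elements that delimit headings, paragraphs
and table parts. Matching semantics are deliberately asymmetric:

* element names match **in full** (`h[1-3]` matches `h2`, never `h20`);
* attribute values match **as substrings** (`section-title.*` matches
  `class="section-title-1 extra"`), because publisher class attributes
  routinely carry generated suffixes.

Heading selectors are ordered, and their list position defines hierarchy
depth: the first selector describes main headers, the second sub-headers,
and so on. This convention replaces any attempt to infer nesting from tag
names, which fails across dialects. Unknown keys in a configuration are
rejected rather than ignored, so typos surface immediately instead of
silently matching nothing.

## Full-text parsing

Parsing is tolerant (libxml2's HTML recovery): real publisher HTML is
frequently malformed, and recovery must never drop text inside matched
containers. The document is walked in reading order; heading matches update
the current heading path at their selector's depth, paragraph matches
become passages, and anything inside a matched table container is left to
the tables module. One recovery artifact deserves note: when a paragraph is
unclosed, parsers may nest following elements (for example a `<figure>`)
*inside* it. Passage text is therefore collected per node while excluding
any descendant subtree that itself matches a paragraph selector — this
guarantees the invariant that every text node under a paragraph selector
lands in exactly one passage, in document order.

Markup stripping removes every tag (emphasis, superscript, subscript),
retains link anchor text, decodes entity references, and collapses
whitespace runs. In full text, `10<sup>3</sup>` flattens to `103`; tables
have their own superscript rule (below).

**Offsets** count UTF-8 code points, starting at 0, cumulatively over the
passage texts retained in the BioC output. Code points rather than bytes
were chosen for encoding stability: byte offsets change when a file is
re-encoded, code points do not. Section titles are stored in passage infons
(`section_title_1`, `section_title_2`, ...), not repeated inside passage
text — title and passage stay directly linked, which fits the
one-section-one-annotation model used for IAO terms.

## Section classification

Three cascading strategies map each main header to IAO document-part
terms; the cascade is strict — if a stage succeeds, later stages are never
consulted for that header.

1. **Lexical.** LOOM-style normalization — lowercase, all non-alphanumeric
   characters removed — followed by exact lookup against the packaged
   lexicon. Normalization-then-equality was chosen over approximate
   delimiter handling for determinism: the same header always resolves the
   same way.
2. **Fuzzy.** The score between normalized strings is
   `2·LCS(a,b)/(|a|+|b|)`, maximized over each entry's label *and*
   synonyms; entries at or above the threshold (default **0.8**) are
   returned in descending order. The formula is pinned (rather than
   delegating to a library's unspecified ratio) so scores are reproducible;
   it is the classic SequenceMatcher-style ratio. At 0.8, a single
   adjacent-letter transposition in any normalized header of five or more
   characters still maps (a swap costs `2/(2n)` of the score).
3. **Digraph prediction.** Each document's main headers form a directed
   path graph (DPG): a linear chain in reading order, consecutive
   duplicates collapsed, no cycles or self-edges. Merging DPGs produces a
   weighted digraph — node and edge weights count publications. For a run
   of consecutive unmapped headers, let A be the nearest preceding mapped
   anchor (a synthetic *document-start* node if none — this mirrors the
   role of a fixed pre-abstract header in some archives and gives leading
   unmapped headers a left anchor) and B the nearest following anchor (or
   none at document end). Candidate assignments are interior nodes of
   digraph paths A→…→B whose interior length equals the run length;
   interior nodes are restricted to IAO-labelled digraph nodes so
   predictions are always ontology terms. Paths are scored by the **sum of
   their edge weights**; ties keep every tied term, so a header may carry
   multiple IAO annotations. Sum-of-weights is an interpretive choice —
   the anchor-bounded assignment is well defined but no scoring rule is
   canonical; summation favors heavily travelled transitions and is
   invariant under the unit increments used to build the graph.

Sub-headers are classified on their own (lexical, then fuzzy); only if
unresolvable do they inherit their main header's terms. A passage's
annotation is that of its deepest resolvable heading.

**Lexicon.** The packaged TSV pins IAO v2020-06-10 document-part terms with
their synonyms plus additions identified from corpus-scale header analysis.
Preferred labels use the "`<category> section`" form used in prose for
these terms ("methods section", "materials section", "patients section");
"abstract" stays bare. Proposed terms that have no published IAO
identifier (disclosure, graphical abstract, highlights, participants, and
the three table-metadata parts) carry provisional `AUTO:` ids; replace the
TSV via `load_lexicon(path)` (or the CLI's `--lexicon` flag) to refresh
against a newer IAO release.

## Table analysis

Only elements matching `table_container` selectors are processed, which is
what separates data tables from layout tables. Each `<table>` is expanded
into a rectangular grid: row/column spans are replicated into every covered
slot, with source-cell identity retained.

* **Headers.** Leading rows with header markup (`<th>`/`<thead>`) are
  navigational; absent any, the first row is taken (a documented
  heuristic — the structural analysis this follows uses richer cues, but
  header markup is near-universal in practice). Multi-row headers are
  joined top-to-bottom with `|`; a spanning header's text is replicated
  once per covered column.
* **Sections.** A *super row* — a single source cell spanning the complete
  row — closes the previous section and names the next. Alternatively,
  when the first column is headerless **and** contains row-spanning cells,
  it is treated as an index (stub) column: each stub cell names the section
  formed by the rows it covers, and the column is consumed. The bare
  "headerless first column" condition alone would make every row a
  divider, hence the row-span requirement; the two modes are applied
  mutually exclusively per block, super rows taking precedence.
* **Column types.** Per cell: numerical if it parses as a number, textual
  if it contains no digits, mixed otherwise; empty cells are
  uninformative. The column type is the modal cell type excluding super
  rows; ties break to mixed, and a column with no informative cells is
  textual by convention.
* **Sub-tables.** Scanning non-super rows top-down, a row in which
  *strictly more than half* of the cells mismatch their column's type is a
  new header row; the rows that follow form a sub-table with identifier
  `N_1`, `N_2`, ... in scan order, metadata copied from the parent, and
  column types re-derived per block (a sub-table's columns need not
  resemble its parent's).
* **Cell values.** Pure numerics become JSON numbers; pure scientific
  notation (`a × 10^b` with superscripted — markup or Unicode — exponent,
  or E-notation) becomes an exponential number; Unicode minus and en-dash
  are accepted as minus signs inside numbers, `×`/`x` as the
  multiplication sign. `true`/`false` stay strings. A comma makes a cell
  non-numeric (thousands conventions vary editorially and are not
  normalized). In strings, superscript is re-encoded as explicit
  `<sup>` markup (`n = 10 <sup>3</sup>`) so positive exponents keep their
  meaning; everything else is flattened. Empty cells are empty strings, so
  row arity is always preserved.
* **Identifiers.** `T<table>.C<col>` for header cells,
  `T<table>.S<section>.R<row>.C<col>` for data cells — section-local,
  1-based row numbering. The scheme is this package's own convention
  (stable, human-readable, unique within a table document).

## Abbreviations

The full-text detector examines every innermost parenthesized span with at
least two non-digit characters. A definition is a run of words adjacent to
the brackets whose first word starts (case-insensitively) with the first
bracket character and whose following words contain the remaining bracket
characters in order; hyphens inside words are transparent (`genome-wide`
provides both `g` and `w` for *GWAS*). The search window is
`min(|short| + 5, 2·|short|)` words per side — the conventional
Schwartz–Hearst bound, adopted because an unbounded scan produces absurd
candidates. The left side is tried first, scanning candidate start words
nearest-the-bracket first so the shortest valid definition wins; at most
one definition per bracket occurrence.

The abbreviations-section detector splits the section on its dominant
delimiter convention, found by trying (item separator, pair delimiter)
combinations from {`;`, newline, `,`} × {`:`, `=`, `,`, `;`} and keeping
the one yielding the most two-sided pairs. One-sided entries are dropped —
an abbreviation without a definition is meaningless downstream. Both
detectors' pairs are merged with per-method provenance: identical pairs
union their methods; a short form with divergent definitions keeps each
long form separately.

## Output comparison (LCS similarity)

Unidirectional similarity `|LCS(ref, cand)|/|ref|` measures how much of a
reference unit survives, in order, in a candidate — non-symmetric by
design, because a richer output (retained link anchor text, say) should not
be penalized. The bidirectional variant takes the maximum of both
directions. Exact dynamic-programming LCS is used per unit (paragraph or
cell); units over 20,000 characters fall back to a banded approximation
(band 2,000) with an explicit flag, never silently. An empty reference
scores 1.0 by convention so missing optional fields do not drag medians
down; each such unit is still visible in the per-unit report. Reports carry
per-unit similarities, the differing reference characters as spans, and
median/IQR aggregates.

## The synthetic-data generator

`gen_article()`/`gen_table()`/`gen_corpus()` emit publisher-style HTML with
byte-exact ground truth, fully determined by the spec's seed. They emulate
the structural phenomena the pipeline exists to handle: heading
hierarchies; typo headers (adjacent-letter swaps kept at fuzzy ratio
≥ 0.8 by construction, with a generation error otherwise); unmapped
headers planted between mappable anchors; abbreviation plants in full
text, in a dedicated section, or both, including divergent definitions;
two-row spanning headers, super rows, stub columns, planted sub-tables,
scientific-notation cells; inline and linked renderings of the same grid;
a "messy" dialect with unclosed tags and span-wrapped text; and encoding
quirks (Unicode dashes, Greek letters). `gen_corpus()` draws section plans
from four realistic templates and computes the expected section digraph by
direct counting over the ground-truth term chains — an oracle independent
of the digraph-accumulation code it is used to test.

What the generator does **not** emulate: publisher-specific boilerplate
(navigation chrome, reference lists, ads), deeply pathological markup,
scanned/image tables, or the long-tail diversity of real section-header
vocabulary. Passing round-trip tests therefore demonstrates the
correctness of the mechanics (parsing, classification cascade, structural
table analysis, serialization) under realistic structure, not performance
on any particular publisher's corpus — for that, a configuration must be
written and spot-checked against real files.

Test and verification sizes are chosen to exercise every variant while
keeping runs quick: 50-article and 50-table fixture matrices, a 50-article
corpus for digraph training/recovery, and thousands of randomized string
pairs against brute-force LCS oracles.

## Degenerate inputs and edge policies

* No selector matches at all → empty model plus a structured warning (the
  signature of a wrong configuration), never an error.
* Empty header list → empty DPG; merging an empty DPG is a no-op.
* A DPG with no mapped anchors → left unmapped, with a warning.
* Headerless grids → empty headers, all rows body, warning.
* Exactly half of a row's cells mismatching → *not* a sub-table split
  (strict `>`).
* `(n)` and `(12)` → no abbreviation (fewer than two non-digit characters).
* Duplicate table identifiers in one article → error (never silently
  renumbered).
* Batch conversion isolates failures per article; the manifest records the
  error and the exit status reflects partial failure.

## Known limitations

* Abbreviations defined *inside* brackets (`magnetic resonance imaging
  (MRI)` works; `MRI (magnetic resonance imaging)` does not) and
  bracket-free definitions are out of scope for the bracket rule.
* Paragraph-content-based classification (for articles without usable
  headers beyond digraph reach) is not attempted.
* The digraph path search enumerates simple paths with a defensive cap; on
  extremely dense digraphs with long unmapped runs the candidate set could
  be truncated (not observed at realistic sizes).
* Scientific notation is only normalized when a cell contains nothing
  else; notation embedded in longer strings is reproduced as-is, so
  cross-publisher notation differences remain visible to `simeval` rather
  than being silently unified.
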