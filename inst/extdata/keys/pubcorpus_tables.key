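{
  "name": "pubcorpus_tables.key",
  "describes": "table JSON output",
  "encoding": "UTF-8",
  "fields": {
    "source": "name of the source configuration used for the conversion",
    "date": "date of the conversion run (YYYYMMDD)",
    "key": "name of this key file",
    "documents": "list of articles",
    "documents[].id": "document identifier",
    "documents[].tables": "data tables; a sub-table (new column headers declared mid-body) is a sibling entry with identifier '<N>_<k>' and metadata identical to its parent",
    "documents[].tables[].identifier": "table number from the title ('Table N'), or position; sub-tables 'N_k'",
    "documents[].tables[].metadata": "three passages labelled with the section types table_title, table_caption, table_footer",
    "documents[].tables[].column_headers": "pipe-joined multi-row column headers; spanning header text replicated per covered column",
    "documents[].tables[].column_headers[].cell_id": "header cell identifier T<table>.C<column> (1-based)",
    "documents[].tables[].sections": "data rows grouped by super-row / index-column section names ('' when unnamed)",
    "documents[].tables[].sections[].rows[][].cell_id": "data cell identifier T<table>.S<section>.R<row>.C<column> (section-local row numbering, 1-based)",
    "documents[].tables[].sections[].rows[][].value": "number (pure numeric or scientific-notation cells) or string; 'true'/'false' stay strings; superscript inside strings is kept as explicit <sup> markup; empty cells are empty strings"
  }
}
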