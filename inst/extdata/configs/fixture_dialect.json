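{
  "source": "fixture_dialect",
  "tables_mode": "both",
  "contributors": ["pubcorpus fixture generator"],
  "selectors": {
    "heading": [
      {"element": "h1", "attrs": {"class": "section-title-1"}},
      {"element": "h2", "attrs": {"class": "section-title-2"}}
    ],
    "paragraph": [
      {"element": "p", "attrs": {"class": "para"}}
    ],
    "table_container": [
      {"element": "div", "attrs": {"class": "table-wrap"}}
    ],
    "table_title": [
      {"element": "p", "attrs": {"class": "table-title"}}
    ],
    "table_caption": [
      {"element": "p", "attrs": {"class": "table-caption"}}
    ],
    "table_footer": [
      {"element": "p", "attrs": {"class": "table-footer"}}
    ]
  }
}
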