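{
  "source": "generic_pmc",
  "tables_mode": "inline",
  "contributors": ["pubcorpus authors"],
  "selectors": {
    "heading": [
      {"element": "h2"},
      {"element": "h3"},
      {"element": "h4"}
    ],
    "paragraph": [
      {"element": "p"}
    ],
    "table_container": [
      {"element": "div", "attrs": {"class": "table-wrap|table_wrap|xtable"}}
    ],
    "table_title": [
      {"element": "div|p|span", "attrs": {"class": "caption-title|table-label"}}
    ],
    "table_caption": [
      {"element": "div|p", "attrs": {"class": "caption"}}
    ],
    "table_footer": [
      {"element": "div|p", "attrs": {"class": "tblwrap-foot|table-foot"}}
    ]
  }
}
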