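{
  "name": "pubcorpus_fulltext.key",
  "describes": "BioC JSON full-text output",
  "encoding": "UTF-8",
  "fields": {
    "source": "name of the source configuration used for the conversion",
    "date": "date of the conversion run (YYYYMMDD)",
    "key": "name of this key file",
    "documents": "list of converted articles",
    "documents[].id": "document identifier (filename stem; PMC accession when present)",
    "documents[].passages": "ordered publication passages",
    "documents[].passages[].offset": "cumulative count of UTF-8 code points of all preceding passage texts, starting at 0",
    "documents[].passages[].text": "plain passage text; all markup removed, link anchor text retained",
    "documents[].passages[].infons.section_title_N": "heading path governing the passage: section title (N=1), subtitle (N=2), and so on",
    "documents[].passages[].infons.iao_name_N": "IAO document-part term name(s) assigned to the passage's section",
    "documents[].passages[].infons.iao_id_N": "IAO identifier matching iao_name_N"
  },
  "notes": [
    "Passages classified as the abbreviations section (IAO:0000606) are stored in the abbreviations JSON, not here.",
    "Structured table data are stored in the table JSON; figure captions are included inline in reading order."
  ]
}
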