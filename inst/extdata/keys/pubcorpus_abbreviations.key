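{
  "name": "pubcorpus_abbreviations.key",
  "describes": "abbreviations JSON output",
  "encoding": "UTF-8",
  "fields": {
    "source": "name of the source configuration used for the conversion",
    "date": "date of the conversion run (YYYYMMDD)",
    "key": "name of this key file",
    "documents": "list of articles",
    "documents[].id": "document identifier",
    "documents[].abbreviations": "map short form -> map long form -> list of detection methods",
    "methods": ["fulltext_bracket", "abbreviations_section"]
  },
  "notes": [
    "The same short form may carry several long forms (e.g. a full-text definition varying from the abbreviations-section definition); each long form lists the method(s) that found it.",
    "One-sided entries (a short form without a definition) are never stored."
  ]
}
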