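{
  "drop_categories": ["Signal transduction"],
  "drop_subcategories": {
    "category": ["Cell envelope", "Central intermediary metabolism"],
    "subcategory": ["Other", "Other"]
  },
  "merge_into_mix": {
    "category": [
      "Cell envelope",
      "Cell envelope",
      "Energy metabolism",
      "Purines, pyrimidines, nucleosides, and nucleotides"
    ],
    "subcategory": [
      "Biosynthesis and degradation of surface polysaccharides and lipopolysaccharides",
      "Biosynthesis of murein sacculus and peptidoglycan",
      "Biosynthesis and degradation of polysaccharides",
      "Sugar-nucleotide biosynthesis and conversions"
    ]
  },
  "mix_name": "Mix category"
}
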