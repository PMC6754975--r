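{
  "matrix_file": "microphthalmid_matrix.nex",
  "characters_file": "microphthalmid_characters.tsv",
  "ntax": 38,
  "nchar": 48,
  "outgroup": ["N. punctata", "O. flexuosus", "S. phuketensis"],
  "label_normalization": {
    "comment": "Taxon labels in the published matrix table that are evident typographical variants of the study's taxon list; fixture uses the normalized form.",
    "M. indefstigstus": "M. indefatigatus",
    "H. pecularis": "H. peculiaris",
    "M. riser": "M. riseri",
    "M. monilicormis": "M. monilicornis",
    "H. indoceanica": "H. indooceanica",
    "M. pseudoaberrans": "M. pseudaberrans",
    "M. ancistrosyllisformis": "M. ancistrosylliformis",
    "S. camposi n. sp.": "S. camposi"
  },
  "notes": [
    "Character 17 (dorsal cirri shape) shows state 3 for S. noodti and S. camposi in the published matrix although only predicates 0-2 are defined for it; the character definition table here carries a fourth placeholder predicate so the matrix validates as printed.",
    "All characters unordered, equal weight; '-' marks inapplicable and '?' missing data, both treated as equivocal in analysis."
  ]
}
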