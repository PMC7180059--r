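{
  "comment": "Default annotation rule base: cardenolide genins, glycoside neutral losses, and glucosinolate targets. Formulas are neutral molecules; masses are recomputed from formulas at load time. Genin set follows the nine aglycones recurrently reported from Erysimum leaf extracts; the dihydroxy-digitoxigenin entry is identified by formula only (isomeric aglycones are indistinguishable by MS).",
  "genins": [
    {"name": "digitoxigenin",            "formula": "C23H34O4"},
    {"name": "cannogenol",               "formula": "C23H34O5"},
    {"name": "cannogenin",               "formula": "C23H32O5"},
    {"name": "strophanthidin",           "formula": "C23H32O6"},
    {"name": "dihydroxy-digitoxigenin",  "formula": "C23H34O6"},
    {"name": "nigrescigenin",            "formula": "C23H32O7"},
    {"name": "acetyl-cannogenol",        "formula": "C25H36O6"},
    {"name": "formyl-cannogenol",        "formula": "C24H34O6"},
    {"name": "formyl-nigrescigenin",     "formula": "C24H32O8"}
  ],
  "sugars": [
    {"name": "digitoxose",  "formula": "C6H10O3"},
    {"name": "deoxyhexose", "formula": "C6H10O4"},
    {"name": "xylose",      "formula": "C5H8O4"},
    {"name": "hexose",      "formula": "C6H10O5"}
  ],
  "acetyl_formula": "C2H2O",
  "glucosinolate_targets": [
    {"name": "glucoiberverin",  "formula": "C11H21NO9S3",  "class": "3C"},
    {"name": "glucoiberin",     "formula": "C11H21NO10S3", "class": "MSI"},
    {"name": "glucocheirolin",  "formula": "C11H21NO11S3", "class": "MSO"},
    {"name": "sinigrin",        "formula": "C10H17NO9S2",  "class": "ALK"},
    {"name": "glucoerucin",     "formula": "C12H23NO9S3",  "class": "4C"},
    {"name": "glucoraphanin",   "formula": "C12H23NO10S3", "class": "MSI"},
    {"name": "glucoerysolin",   "formula": "C12H23NO11S3", "class": "MSO"},
    {"name": "glucoerypestrin", "formula": "C12H21NO11S2", "class": "CARB"},
    {"name": "glucobrassicin",  "formula": "C16H20N2O9S2", "class": "IND"},
    {"name": "2OH-propyl-GSL",  "formula": "C10H19NO10S2", "class": "OH"}
  ],
  "diagnostic_fragments_neg": [96.9601, 95.9528, 74.9915, 259.0129, 241.0024]
}
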