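{
  "comment": "Parent compound definitions: canonical SMILES, Hill formula, structural prerequisite tags for the rule engine, metabolite-ID prefix, parent retention time (min), and the biotransformation-stage registry mapping a canonical chain class (sorted rule names joined by '+'; '' = parent) to the stage number used in metabolite identifiers. cross_reactivity lists metabolite labels shared with structurally related compounds (nonspecific biomarkers).",
  "parents": [
    {
      "name": "ADMB-3TMS-PrINACA",
      "label_prefix": "A",
      "smiles": "O=C(C1=NN(CCC[Si](C)(C)C)C2=C1C=CC=C2)NC(C(C)(C)C)C(N)=O",
      "formula": "C20H32N4O2Si",
      "tags": ["requires_Si", "requires_3TMS", "requires_primary_amide"],
      "rt_min": 13.10,
      "stage_registry": {
        "": 0,
        "hydroxylation": 1,
        "amide_hydrolysis": 2,
        "dihydroxylation": 3,
        "hydroxylation+hydroxylation": 3,
        "trihydroxylation": 4,
        "dihydroxylation+hydroxylation": 4,
        "hydroxylation+hydroxylation+hydroxylation": 4,
        "hydroxylation+ketone_aldehyde_formation": 5,
        "carboxylic_acid_formation+hydroxylation": 6,
        "si_demethylation": 7,
        "cleavage_3tms_terminal_hydroxylation": 8,
        "cleavage_3tms_terminal_hydroxylation+ketone_aldehyde_formation": 9,
        "carboxylic_acid_formation+cleavage_3tms_terminal_hydroxylation": 10,
        "demethylation+hydroxylation": 11,
        "hydroxylation+si_demethylation": 11,
        "demethylation+dihydroxylation": 12,
        "demethylation+hydroxylation+hydroxylation": 12,
        "dihydroxylation+si_demethylation": 12,
        "hydroxylation+hydroxylation+si_demethylation": 12,
        "n_dealkylation": 13,
        "amide_hydrolysis+hydroxylation": 14
      },
      "cross_reactivity": {}
    },
    {
      "name": "Cumyl-3TMS-PrINACA",
      "label_prefix": "C",
      "smiles": "O=C(NC(C)(C)C1=CC=CC=C1)C2=NN(CCC[Si](C)(C)C)C3=CC=CC=C32",
      "formula": "C23H31N3OSi",
      "tags": ["requires_Si", "requires_3TMS"],
      "rt_min": 16.02,
      "stage_registry": {
        "": 0,
        "hydroxylation": 1,
        "dihydroxylation": 2,
        "hydroxylation+hydroxylation": 2,
        "trihydroxylation": 3,
        "dihydroxylation+hydroxylation": 3,
        "hydroxylation+hydroxylation+hydroxylation": 3,
        "si_demethylation": 4,
        "demethylation+hydroxylation": 5,
        "hydroxylation+si_demethylation": 5,
        "cleavage_3tms_terminal_hydroxylation": 6,
        "cleavage_3tms_terminal_hydroxylation+ketone_aldehyde_formation": 7,
        "carboxylic_acid_formation+cleavage_3tms_terminal_hydroxylation": 8,
        "hydroxylation+ketone_aldehyde_formation": 9,
        "carboxylic_acid_formation+hydroxylation": 10,
        "demethylation+dihydroxylation": 11,
        "demethylation+hydroxylation+hydroxylation": 11,
        "dihydroxylation+si_demethylation": 11,
        "hydroxylation+hydroxylation+si_demethylation": 11,
        "n_dealkylation": 12
      },
      "cross_reactivity": {
        "Cumyl-PINACA": ["C6", "C8"],
        "5F-Cumyl-PINACA": ["C6"]
      }
    }
  ]
}
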