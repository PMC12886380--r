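{
  "kb_version": "1.0",
  "comment": "Diagnostic product-ion knowledge base. 'fragments' are the curated parent-compound inventories (composition given as a Hill formula of the cation's atom inventory; m/z derived at load time as monoisotopic mass minus one electron mass). moieties says which structural units the cation contains, which drives fragment-shift localization. 'literal' fragments carry only an annotated m/z (no modeled composition). 'inferred' entries are metabolite-class ions whose compositions were back-calculated from the printed m/z within 5 ppm and must not be treated as ground truth.",
  "fragments": [
    {
      "name": "trimethylsilyl_cation", "parent": "ADMB-3TMS-PrINACA",
      "composition": "C3H9Si", "moieties": ["side_chain"], "flags": []
    },
    {
      "name": "indazole_acylium", "parent": "ADMB-3TMS-PrINACA",
      "composition": "C8H5N2O", "moieties": ["core", "linker"], "flags": []
    },
    {
      "name": "indazolyl_acylium_3tms", "parent": "ADMB-3TMS-PrINACA",
      "composition": "C14H19N2OSi", "moieties": ["core", "side_chain", "linker"], "flags": []
    },
    {
      "name": "alpha_cleavage", "parent": "ADMB-3TMS-PrINACA",
      "composition": "C19H30N3OSi",
      "moieties": ["core", "side_chain", "linker", "head_group"], "flags": []
    },
    {
      "name": "n_o_exchange", "parent": "ADMB-3TMS-PrINACA",
      "literal_mz": 277.1367, "moieties": ["core", "side_chain"],
      "flags": ["annotated_only"]
    },
    {
      "name": "trimethylsilyl_cation", "parent": "Cumyl-3TMS-PrINACA",
      "composition": "C3H9Si", "moieties": ["side_chain"], "flags": []
    },
    {
      "name": "tropylium", "parent": "Cumyl-3TMS-PrINACA",
      "composition": "C7H7", "moieties": ["head_group"], "flags": []
    },
    {
      "name": "cumyl", "parent": "Cumyl-3TMS-PrINACA",
      "composition": "C9H11", "moieties": ["head_group"], "flags": []
    },
    {
      "name": "indazole_acylium", "parent": "Cumyl-3TMS-PrINACA",
      "composition": "C8H5N2O", "moieties": ["core", "linker"], "flags": []
    },
    {
      "name": "indazolyl_acylium_3tms", "parent": "Cumyl-3TMS-PrINACA",
      "composition": "C14H19N2OSi", "moieties": ["core", "side_chain", "linker"], "flags": []
    }
  ],
  "inferred": [
    {"parent": "ADMB-3TMS-PrINACA", "chain_class": "hydroxylation",
     "name": "hydroxy_259_plus_h2o", "composition": "C14H21N2O3Si", "flags": ["inferred"]},
    {"parent": "ADMB-3TMS-PrINACA", "chain_class": "dihydroxylation",
     "name": "dihydroxy_259_minus_h2o", "composition": "C14H17N2O2Si", "flags": ["inferred"]},
    {"parent": "ADMB-3TMS-PrINACA", "chain_class": "cleavage_3tms_terminal_hydroxylation",
     "name": "a8_amide_ion", "composition": "C11H14N3O2", "flags": ["inferred"]},
    {"parent": "ADMB-3TMS-PrINACA", "chain_class": "cleavage_3tms_terminal_hydroxylation",
     "name": "a8_alpha_minus_formamide", "composition": "C16H22N3O2", "flags": ["inferred"]},
    {"parent": "ADMB-3TMS-PrINACA", "chain_class": "carboxylic_acid_formation+cleavage_3tms_terminal_hydroxylation",
     "name": "a10_amide_ion", "composition": "C11H12N3O3", "flags": ["inferred"]},
    {"parent": "ADMB-3TMS-PrINACA", "chain_class": "carboxylic_acid_formation+cleavage_3tms_terminal_hydroxylation",
     "name": "a10_alpha_minus_formamide", "composition": "C16H20N3O3", "flags": ["inferred"]},
    {"parent": "ADMB-3TMS-PrINACA", "chain_class": "demethylation+dihydroxylation",
     "name": "a12_277_minus_h2o", "composition": "C13H15N2O2Si", "flags": ["inferred"]},
    {"parent": "Cumyl-3TMS-PrINACA", "chain_class": "demethylation+dihydroxylation",
     "name": "c11_277_minus_h2o", "composition": "C13H15N2O2Si", "flags": ["inferred"]},
    {"parent": "Cumyl-3TMS-PrINACA", "chain_class": "demethylation+hydroxylation",
     "name": "c5_261_plus_nh3", "composition": "C13H20N3O2Si", "flags": ["inferred"]}
  ],
  "ei_nominal": {
    "shared": [73, 103, 131, 145, 259],
    "Cumyl-3TMS-PrINACA": [91, 119, 393]
  }
}
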