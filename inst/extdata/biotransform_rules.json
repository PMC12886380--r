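{
  "registry_version": "1.0",
  "comment": "Phase I/II biotransformation rules. gain/loss are Hill formulas ('' = none). prerequisite is a structural tag that must be present before application; grants/revokes update the tag set along a chain. site_tags are the locations a rule may act on (S side chain, H head group, C core).",
  "rules": [
    {
      "name": "hydroxylation",
      "gain": "O", "loss": "",
      "prerequisite": "none",
      "grants": ["requires_hydroxyl"], "revokes": [],
      "site_tags": ["S", "H", "C", "unknown"],
      "phase": "I", "max_applications": 3
    },
    {
      "name": "dihydroxylation",
      "gain": "O2", "loss": "",
      "prerequisite": "none",
      "grants": ["requires_hydroxyl"], "revokes": [],
      "site_tags": ["S", "H", "C", "unknown"],
      "phase": "I", "max_applications": 1
    },
    {
      "name": "trihydroxylation",
      "gain": "O3", "loss": "",
      "prerequisite": "none",
      "grants": ["requires_hydroxyl"], "revokes": [],
      "site_tags": ["S", "H", "C", "unknown"],
      "phase": "I", "max_applications": 1
    },
    {
      "name": "ketone_aldehyde_formation",
      "gain": "", "loss": "H2",
      "prerequisite": "requires_hydroxyl",
      "grants": [], "revokes": ["requires_hydroxyl"],
      "site_tags": ["S", "H", "unknown"],
      "phase": "I", "max_applications": 1
    },
    {
      "name": "carboxylic_acid_formation",
      "gain": "O", "loss": "H2",
      "prerequisite": "requires_hydroxyl",
      "grants": [], "revokes": ["requires_hydroxyl"],
      "site_tags": ["S", "H", "unknown"],
      "phase": "I", "max_applications": 1
    },
    {
      "name": "demethylation",
      "gain": "", "loss": "CH2",
      "prerequisite": "none",
      "grants": [], "revokes": [],
      "site_tags": ["S", "H", "unknown"],
      "phase": "I", "max_applications": 1
    },
    {
      "name": "si_demethylation",
      "gain": "", "loss": "CH2",
      "prerequisite": "requires_Si",
      "grants": ["requires_hydroxyl"], "revokes": [],
      "site_tags": ["S"],
      "phase": "I", "max_applications": 1
    },
    {
      "name": "cleavage_3tms_terminal_hydroxylation",
      "gain": "O", "loss": "C3H8Si",
      "prerequisite": "requires_3TMS",
      "grants": ["requires_hydroxyl"], "revokes": ["requires_Si", "requires_3TMS"],
      "site_tags": ["S"],
      "phase": "I", "max_applications": 1
    },
    {
      "name": "n_dealkylation",
      "gain": "", "loss": "C6H14Si",
      "prerequisite": "requires_3TMS",
      "grants": [], "revokes": ["requires_Si", "requires_3TMS"],
      "site_tags": ["S"],
      "phase": "I", "max_applications": 1
    },
    {
      "name": "amide_hydrolysis",
      "gain": "O", "loss": "HN",
      "prerequisite": "requires_primary_amide",
      "grants": [], "revokes": ["requires_primary_amide"],
      "site_tags": ["H"],
      "phase": "I", "max_applications": 1,
      "flags": ["tentative"]
    },
    {
      "name": "o_glucuronidation",
      "gain": "C6H8O6", "loss": "",
      "prerequisite": "requires_hydroxyl",
      "grants": [], "revokes": [],
      "site_tags": ["S", "H", "C", "unknown"],
      "phase": "II", "max_applications": 1
    }
  ]
}
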