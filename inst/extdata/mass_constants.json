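{
  "comment": "Monoisotopic atomic masses (Da, CODATA/IUPAC) and integer nominal masses for the supported element set, plus the electron mass. Values are documented to >= 6 decimal places and treated as immutable.",
  "monoisotopic": {
    "C": 12.0,
    "H": 1.0078250319,
    "N": 14.0030740052,
    "O": 15.9949146221,
    "Si": 27.9769265327,
    "Na": 22.9897692820,
    "S": 31.9720706900,
    "P": 30.9737615120,
    "F": 18.9984031630,
    "Cl": 34.9688527100,
    "Br": 78.9183376000,
    "I": 126.9044730000
  },
  "nominal": {
    "C": 12,
    "H": 1,
    "N": 14,
    "O": 16,
    "Si": 28,
    "Na": 23,
    "S": 32,
    "P": 31,
    "F": 19,
    "Cl": 35,
    "Br": 79,
    "I": 127
  },
  "electron": 0.0005485799
}
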