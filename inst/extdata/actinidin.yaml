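# Positional substrate-specificity definition for actinidin
# (Schechter-Berger P4..P4' nomenclature). Two evidence sources:
# cleavage positions observed on kiwellin, and on the insulin B chain.
# A position absent from a source is unconstrained for that source.
# Residue letters are quoted: bare T/F/Y/N would parse as YAML booleans.
name: actinidin
combination: any_source
sources:
  kiwellin:
    "P1":  ["T", "H", "R"]
    "P1'": ["T", "S", "G"]
  insulin:
    "P4":  ["G", "A", "S", "P", "E", "K", "R", "H"]
    "P3":  ["G", "P", "A", "F", "L", "S", "K", "H"]
    "P2":  ["F", "A", "V", "L", "S", "M", "Y", "D", "E"]
    "P1":  ["G", "A", "F", "Y", "R", "V", "N", "Q", "E", "K", "H"]
    "P1'": ["G", "V", "L", "Y", "S", "T", "Q", "D", "E"]
    "P2'": ["P", "F", "A", "V", "H", "G", "M", "T"]
    "P3'": ["G", "L", "F", "P", "V", "D", "E", "K"]
    "P4'": ["P", "A", "Y", "G", "V", "L", "D", "K"]
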