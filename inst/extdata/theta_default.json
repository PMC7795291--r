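{
  "comment": "Default side-chain atoms defining the theta torsion atom1-CA1-CA2-atom2. Editable convention; the middle atoms are always the alpha carbons of monomers 1 and 2.",
  "ASP": {"atom1": "CG", "atom2": "CG"},
  "HIS": {"atom1": "CE1", "atom2": "CE1"},
  "CYS": {"atom1": "SG", "atom2": "SG"},
  "LYS": {"atom1": "NZ", "atom2": "NZ"}
}
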