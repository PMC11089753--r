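{
  "comment": "Interaction-typing rule tables. Protein rules are side-chain atom-name tables per standard residue; ligand rules are structural predicates applied by the package (acceptor: heavy N/O; hydrophobic: carbon bonded only to carbon or hydrogen; pi_stacking: atom on an aromatic bond). The protein hydrophobic table lists the side-chain carbons whose bonded heavy neighbours are all carbons in the standard residue topologies, i.e. the same predicate evaluated on template connectivity.",
  "protein_donor": {
    "ARG": ["NE", "NH1", "NH2"],
    "LYS": ["NZ"],
    "HIS": ["ND1", "NE2"],
    "TRP": ["NE1"],
    "ASN": ["ND2"],
    "GLN": ["NE2"],
    "SER": ["OG"],
    "THR": ["OG1"],
    "TYR": ["OH"]
  },
  "protein_hydrophobic": {
    "ALA": ["CB"],
    "ARG": ["CB", "CG"],
    "ASN": ["CB"],
    "ASP": ["CB"],
    "GLN": ["CB", "CG"],
    "GLU": ["CB", "CG"],
    "ILE": ["CB", "CG1", "CG2", "CD1"],
    "LEU": ["CB", "CG", "CD1", "CD2"],
    "LYS": ["CB", "CG", "CD"],
    "MET": ["CB"],
    "PHE": ["CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"],
    "PRO": ["CB", "CG"],
    "THR": ["CG2"],
    "TRP": ["CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"],
    "TYR": ["CB", "CG", "CD1", "CD2", "CE1", "CE2"],
    "VAL": ["CB", "CG1", "CG2"]
  },
  "protein_pi_stacking": {
    "PHE": ["CG", "CD1", "CD2", "CE1", "CE2", "CZ"],
    "TYR": ["CG", "CD1", "CD2", "CE1", "CE2", "CZ"],
    "TRP": ["CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"],
    "HIS": ["CG", "ND1", "CD2", "CE1", "NE2"]
  },
  "backbone_atoms": ["N", "CA", "C", "O", "OXT"]
}
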