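# Single-domain water-soluble control: rap1 BRCT domain (PDB 2L42, NMR;
# model 1 used by default). 97 residues, scored as one unit.
structure: 2l42.pdb
model: 1
selections:
  - {name: BRCT, mode: chain, units: "A"}
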