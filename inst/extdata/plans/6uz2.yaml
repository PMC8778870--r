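# Analysis grid for MsbA-1 (PDB 6UZ2): lipid-A transporter homodimer in
# beta-dodecylmaltoside. The source table labels the domains DD1/DD2 and
# D1/D2 without printing residue ranges; the boundaries below follow the
# standard E. coli MsbA architecture (transmembrane domain ~1-320,
# nucleotide-binding domain ~321-582) and are a reconstruction, not a
# published table value.
structure: 6uz2.pdb
selections:
  - {name: "Chains A+B", mode: complex, units: "A,B"}
  - {name: DD1, mode: domain_set, units: "A:1-320,B:1-320"}
  - {name: DD2, mode: domain_set, units: "A:321-582,B:321-582"}
  - {name: "Chain A", mode: chain, units: "A"}
  - {name: D1, mode: individual_domain, units: "A:1-320"}
  - {name: D2, mode: individual_domain, units: "A:321-582"}
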