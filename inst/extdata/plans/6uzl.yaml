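# Analysis grid for MsbA-2 (PDB 6UZL): lipid-A transporter homodimer in
# beta-dodecylmaltoside. Domain ranges reconstructed as in 6uz2.yaml.
structure: 6uzl.pdb
selections:
  - {name: "Chains A+B", mode: complex, units: "A,B"}
  - {name: DD1, mode: domain_set, units: "A:1-320,B:1-320"}
  - {name: DD2, mode: domain_set, units: "A:321-582,B:321-582"}
  - {name: "Chain A", mode: chain, units: "A"}
  - {name: D1, mode: individual_domain, units: "A:1-320"}
  - {name: D2, mode: individual_domain, units: "A:321-582"}
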