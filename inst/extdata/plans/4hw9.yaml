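# Analysis grid for HpMscS (PDB 4HW9): heptameric small-conductance
# mechanosensitive channel. Domain boundaries in author numbering.
# Place the structure file next to this plan (4hw9.pdb) or pass it
# explicitly. Note: the published domain table gives the fourth domain as
# 261-272 at the domain-set level but 261-267 at the single-chain/individual
# level; both are kept here as printed, the inconsistency is in the source
# table itself.
structure: 4hw9.pdb
selections:
  - {name: Complex, mode: complex, units: "A,B,C,D,E,F,G"}
  - {name: DD1, mode: domain_set,
     units: "A:18-116,B:18-116,C:18-116,D:18-116,E:18-116,F:18-116,G:18-116"}
  - {name: DD2, mode: domain_set,
     units: "A:117-171,B:117-171,C:117-171,D:117-171,E:117-171,F:117-171,G:117-171"}
  - {name: DD3, mode: domain_set,
     units: "A:172-260,B:172-260,C:172-260,D:172-260,E:172-260,F:172-260,G:172-260"}
  - {name: DD4, mode: domain_set,
     units: "A:261-272,B:261-272,C:261-272,D:261-272,E:261-272,F:261-272,G:261-272"}
  - {name: "frag chain 18-272", mode: fragment_in_complex,
     units: "A:18-272", parent: Complex}
  - {name: "frag 18-116", mode: fragment_in_complex,
     units: "A:18-116,B:18-116,C:18-116,D:18-116,E:18-116,F:18-116,G:18-116",
     parent: Complex}
  - {name: "frag 117-171", mode: fragment_in_complex,
     units: "A:117-171,B:117-171,C:117-171,D:117-171,E:117-171,F:117-171,G:117-171",
     parent: Complex}
  - {name: "frag 172-260", mode: fragment_in_complex,
     units: "A:172-260,B:172-260,C:172-260,D:172-260,E:172-260,F:172-260,G:172-260",
     parent: Complex}
  - {name: "frag 261-272", mode: fragment_in_complex,
     units: "A:261-272,B:261-272,C:261-272,D:261-272,E:261-272,F:261-272,G:261-272",
     parent: Complex}
  - {name: "Chain A", mode: chain, units: "A:18-272"}
  - {name: "chain frag 18-116", mode: fragment_in_complex,
     units: "A:18-116", parent: "Chain A"}
  - {name: "chain frag 117-171", mode: fragment_in_complex,
     units: "A:117-171", parent: "Chain A"}
  - {name: "chain frag 172-260", mode: fragment_in_complex,
     units: "A:172-260", parent: "Chain A"}
  - {name: "chain frag 261-267", mode: fragment_in_complex,
     units: "A:261-267", parent: "Chain A"}
  - {name: D1, mode: individual_domain, units: "A:18-116"}
  - {name: D2, mode: individual_domain, units: "A:117-171"}
  - {name: D3, mode: individual_domain, units: "A:172-260"}
  - {name: D4, mode: individual_domain, units: "A:261-267"}
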