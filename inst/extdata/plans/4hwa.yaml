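# Analysis grid for EcMscS (PDB 4HWA): heptameric small-conductance
# mechanosensitive channel (open form). Author numbering.
structure: 4hwa.pdb
selections:
  - {name: Complex, mode: complex, units: "A,B,C,D,E,F,G"}
  - {name: DD1, mode: domain_set,
     units: "A:25-126,B:25-126,C:25-126,D:25-126,E:25-126,F:25-126,G:25-126"}
  - {name: DD2, mode: domain_set,
     units: "A:127-179,B:127-179,C:127-179,D:127-179,E:127-179,F:127-179,G:127-179"}
  - {name: DD3, mode: domain_set,
     units: "A:180-270,B:180-270,C:180-270,D:180-270,E:180-270,F:180-270,G:180-270"}
  - {name: DD4, mode: domain_set,
     units: "A:271-280,B:271-280,C:271-280,D:271-280,E:271-280,F:271-280,G:271-280"}
  - {name: "frag chain 25-280", mode: fragment_in_complex,
     units: "A:25-280", parent: Complex}
  - {name: "frag 25-126", mode: fragment_in_complex,
     units: "A:25-126,B:25-126,C:25-126,D:25-126,E:25-126,F:25-126,G:25-126",
     parent: Complex}
  - {name: "frag 127-179", mode: fragment_in_complex,
     units: "A:127-179,B:127-179,C:127-179,D:127-179,E:127-179,F:127-179,G:127-179",
     parent: Complex}
  - {name: "frag 180-270", mode: fragment_in_complex,
     units: "A:180-270,B:180-270,C:180-270,D:180-270,E:180-270,F:180-270,G:180-270",
     parent: Complex}
  - {name: "frag 271-280", mode: fragment_in_complex,
     units: "A:271-280,B:271-280,C:271-280,D:271-280,E:271-280,F:271-280,G:271-280",
     parent: Complex}
  - {name: "Chain A", mode: chain, units: "A:25-280"}
  - {name: "chain frag 25-126", mode: fragment_in_complex,
     units: "A:25-126", parent: "Chain A"}
  - {name: "chain frag 127-179", mode: fragment_in_complex,
     units: "A:127-179", parent: "Chain A"}
  - {name: "chain frag 180-270", mode: fragment_in_complex,
     units: "A:180-270", parent: "Chain A"}
  - {name: "chain frag 271-280", mode: fragment_in_complex,
     units: "A:271-280", parent: "Chain A"}
  - {name: D1, mode: individual_domain, units: "A:25-126"}
  - {name: D2, mode: individual_domain, units: "A:127-179"}
  - {name: D3, mode: individual_domain, units: "A:180-270"}
  - {name: D4, mode: individual_domain, units: "A:271-280"}
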