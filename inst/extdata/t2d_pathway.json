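{
  "comment": "Insulin-resistance-focused slice of the KEGG type 2 diabetes mellitus pathway (hsa04930), hand-encoded. Entities are listed as printed in the source pathway; edge and chain endpoints use normalized merged labels (IRS1/IRS, TNFA, PKCZ, ERK1/2). Expansion chains spell out each indirect interaction through its auxiliary pathway; consecutive chain pairs marked 'undirected' are associations that enter the extended network but not the directed evaluation set.",
  "entities": [
    {"id": "ADIPO", "type": "gene"},
    {"id": "GLUT4", "type": "gene"},
    {"id": "INS", "type": "gene"},
    {"id": "INSR", "type": "gene"},
    {"id": "IRS1", "type": "gene"},
    {"id": "IRS", "type": "gene"},
    {"id": "PI3K", "type": "gene"},
    {"id": "SOCS", "type": "gene"},
    {"id": "ERK", "type": "gene"},
    {"id": "TNF-alpha", "type": "gene"},
    {"id": "IKK", "type": "gene"},
    {"id": "JNK", "type": "gene"},
    {"id": "mTOR", "type": "gene"},
    {"id": "PRKCZ", "type": "gene"},
    {"id": "PKCD/E", "type": "gene"},
    {"id": "Obesity", "type": "disease"},
    {"id": "Transient hyperglycemia", "type": "disease"},
    {"id": "Type 2 diabetes mellitus", "type": "disease"},
    {"id": "FFA", "type": "molecular_function"}
  ],
  "edges": [
    {"source": "ADIPO", "target": "GLUT4", "interaction": "indirect", "directed": true, "participating_pathway": "Adipocytokine signaling pathway"},
    {"source": "INS", "target": "INSR", "interaction": "direct", "directed": true, "participating_pathway": null},
    {"source": "INSR", "target": "IRS1/IRS", "interaction": "direct", "directed": true, "participating_pathway": null},
    {"source": "IRS1/IRS", "target": "PI3K", "interaction": "direct", "directed": true, "participating_pathway": null},
    {"source": "INSR", "target": "SOCS", "interaction": "direct", "directed": true, "participating_pathway": null},
    {"source": "SOCS", "target": "IRS1/IRS", "interaction": "direct", "directed": true, "participating_pathway": null},
    {"source": "INSR", "target": "ERK1/2", "interaction": "indirect", "directed": true, "participating_pathway": "Insulin signaling pathway"},
    {"source": "ERK1/2", "target": "IRS1/IRS", "interaction": "indirect", "directed": true, "participating_pathway": "Insulin signaling pathway"},
    {"source": "PI3K", "target": "GLUT4", "interaction": "indirect", "directed": true, "participating_pathway": "Insulin signaling pathway"},
    {"source": "PI3K", "target": "mTOR", "interaction": "indirect", "directed": true, "participating_pathway": "Insulin signaling pathway"},
    {"source": "PI3K", "target": "PKCZ", "interaction": "indirect", "directed": true, "participating_pathway": "Insulin signaling pathway"},
    {"source": "TNFA", "target": "IKK", "interaction": "indirect", "directed": true, "participating_pathway": "Adipocytokine signaling pathway"},
    {"source": "TNFA", "target": "JNK", "interaction": "indirect", "directed": true, "participating_pathway": "Adipocytokine signaling pathway"},
    {"source": "TNFA", "target": "mTOR", "interaction": "indirect", "directed": true, "participating_pathway": "Adipocytokine signaling pathway"},
    {"source": "IKK", "target": "IRS1/IRS", "interaction": "direct", "directed": true, "participating_pathway": null},
    {"source": "JNK", "target": "IRS1/IRS", "interaction": "direct", "directed": true, "participating_pathway": null},
    {"source": "PKCZ", "target": "IRS1/IRS", "interaction": "direct", "directed": true, "participating_pathway": null},
    {"source": "PKCD/E", "target": "IRS1/IRS", "interaction": "direct", "directed": true, "participating_pathway": null}
  ],
  "expansions": [
    {"source": "ADIPO", "target": "GLUT4",
     "chain": ["ADIPO", "ADIPOR", "AMPKK", "AMPK", "GLUT4"],
     "undirected": [["ADIPOR", "AMPKK"], ["AMPK", "GLUT4"]]},
    {"source": "INSR", "target": "ERK1/2",
     "chain": ["INSR", "SHC", "GRB2", "SOS", "Ras", "Raf", "MEK1/2", "ERK1/2"],
     "undirected": []},
    {"source": "ERK1/2", "target": "IRS1/IRS",
     "chain": ["IRS1/IRS", "GRB2", "SOS", "Ras", "Raf", "MEK1/2", "ERK1/2"],
     "undirected": []},
    {"source": "PI3K", "target": "GLUT4",
     "chain": ["PI3K", "PDK1/2", "AKT", "GLUT4"],
     "undirected": []},
    {"source": "PI3K", "target": "GLUT4",
     "chain": ["PI3K", "PDK1/2", "PKCZ", "GLUT4"],
     "undirected": []},
    {"source": "PI3K", "target": "mTOR",
     "chain": ["PI3K", "PDK1/2", "AKT", "mTOR"],
     "undirected": []},
    {"source": "PI3K", "target": "PKCZ",
     "chain": ["PI3K", "PDK1/2", "PKCZ"],
     "undirected": []},
    {"source": "TNFA", "target": "IKK",
     "chain": ["TNFA", "TNFR1", "TRADD", "TNFR2", "TRAF2", "IKK"],
     "undirected": [["TRAF2", "IKK"]]},
    {"source": "TNFA", "target": "JNK",
     "chain": ["TNFA", "TNFR2", "TRAF2", "JNK"],
     "undirected": [["TRAF2", "JNK"]]},
    {"source": "TNFA", "target": "mTOR",
     "chain": ["TNFA", "TNFR1", "TRADD", "TNFR2", "TRAF2", "mTOR"],
     "undirected": [["TRAF2", "mTOR"]]}
  ]
}
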