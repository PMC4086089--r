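{
  "comment": "Default chemical-identity rules for ligand classification. Order matters: the first matching list wins. Curated overrides always take precedence over these rules. The lists below are package defaults assembled from common crystallization additives and cofactors; they are data, not code, and can be replaced via the rules argument.",
  "solvent_ions": ["K", "NA", "CL", "BR", "IOD", "CS", "LI", "NO3", "SO4", "PO4", "ACT", "CAC"],
  "buffers_cryoprotectants": ["GOL", "EDO", "PEG", "PG4", "PGE", "MPD", "DMS", "TRS", "EPE", "MES", "BME", "DTT", "FMT", "ACY"],
  "cofactors": ["HEM", "HEC", "FAD", "FMN", "NAD", "NAP", "NDP", "ATP", "ADP", "AMP", "GTP", "GDP", "GMP", "SAM", "SAH", "PLP", "TPP", "COA", "SF4", "FES", "F3S", "B12", "CLA", "BCL", "RET"],
  "functional_metals": ["ZN", "FE", "FE2", "MN", "CU", "CU1", "MG", "CA", "CO", "NI", "MO"]
}
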