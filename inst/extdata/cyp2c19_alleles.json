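{
  "gene": "CYP2C19",
  "build": "GRCh37",
  "region_start": 95522463,
  "region_end": 97612671,
  "note": "Synthetic reconstruction of a minimal CYP2C19 star-allele panel: real rsIDs and GRCh37 coordinates, CPIC-style function classes; not a copy of any single published definition file."
}
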