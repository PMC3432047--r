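# Phenol as sole carbon source at the same molar uptake as glucose.
name: phenol
uptakes:
  EX_phenol_e: 0.55
ngam: 1.9
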