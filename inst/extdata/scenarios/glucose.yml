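# Heterotrophic reference condition: measured glucose uptake, NGAM fitted
# to the observed 25% carbon usage ratio.
name: glucose
uptakes:
  EX_glc_e: 0.55
ngam: 1.9
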