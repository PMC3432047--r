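# Autotrophic bicarbonate fixation: same carbon uptake as 0.55 glucose
# (3.3 mmol C), hydrogen sulfide unconstrained as electron donor.
name: hco3_fixation
uptakes:
  EX_hco3_e: 3.3
  EX_h2s_e: 100000
ngam: 1.9
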