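# Glucose growth with 22.5% of imported carbon routed into exopolysaccharide
# (EPS flux 0.049 = 0.225 * 0.55 * 6 / 15.06 carbon atoms per EPS unit).
name: glucose_eps
uptakes:
  EX_glc_e: 0.55
ngam: 1.9
fixed:
  R_eps: 0.049
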