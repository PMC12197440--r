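# Reference values for drug standards run alongside samples.
metformin:
  standard_rf: 0.604
  label_claim_mg: 500
  tolerance_frac: 0.10
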