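# Example run configuration: palmitoleate feeding with a larger acyl-CoA
# clamp and slightly weaker ACC feedback. Unlisted parameters keep the
# calibrated defaults (see ?fa_default_params).
model:
  acc:
    ki: 1.5
protocol:
  fatty_acid: palmitoleate
  clamp_value: 12
seed: 4
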