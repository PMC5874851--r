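water:
  name: water
  density: 1.0
  radiation_length_mass: 36.08
  range_coeff_alpha: 0.0022808
  range_exponent_p: 1.7627798
lexan:
  name: lexan
  density: 1.2
  radiation_length_mass: 41.5
  range_coeff_alpha: 0.0019912
  range_exponent_p: 1.7631997
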