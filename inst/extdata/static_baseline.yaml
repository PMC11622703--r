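# Pre-intervention static lighting: mean illuminance (lux) per area type.
static_baseline:
  bathroom: 99
  bedroom: 75
  kitchenette_living: 59.33
  common_area: 147
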