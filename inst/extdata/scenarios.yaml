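# Bundled experimental conditions for the reduced leaf model.
# Chlorophyll export is fixed at 1.0 flux unit in every scenario.
case1:
  fixed: {chlorophyll_tx: 1.0}
  blocked: [chl_RBC_oxy]
case2:
  fixed: {chlorophyll_tx: 1.0}
  ratios:
    - {a: chl_RBC_carb, b: chl_RBC_oxy, r: 3.0}
case1-diffusion:
  fixed: {chlorophyll_tx: 1.0}
  blocked: [chl_RBC_oxy]
  bounds: {am_diff_tx: [0.0, 1000.0]}
case2-diffusion:
  fixed: {chlorophyll_tx: 1.0}
  ratios:
    - {a: chl_RBC_carb, b: chl_RBC_oxy, r: 3.0}
  bounds: {am_diff_tx: [0.0, 1000.0]}
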