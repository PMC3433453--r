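# Packaged global inputs: per-ecosystem published ranges (min, central, max).
# Extent in Mha; conversion rate in %/yr; stocks in Mg C/ha with the total
# near-surface stock given directly in Mg CO2/ha as printed; loss fraction
# dimensionless (central defaults to the midpoint, 0.625).
ecosystems:
  tidal_marsh:
    extent: {min: 2.2, central: 5.1, max: 40.0, family: gamma, gamma_shape: 1.6, gamma_scale: 6.0}
    rate: {min: 1.0, central: 1.5, max: 2.0}
    stocks: {sediment_c: 250.0, biomass_c: 9.0, total_co2: 949.0}
    loss: {min: 0.25, max: 1.0}
  mangrove:
    extent: {min: 13.8, central: 14.5, max: 15.2, family: normal}
    rate: {min: 0.7, central: 1.9, max: 3.0}
    stocks: {sediment_c: 280.0, biomass_c: 127.0, total_co2: 1492.0}
    loss: {min: 0.25, max: 1.0}
  seagrass:
    extent: {min: 17.7, central: 30.0, max: 60.0, family: gamma, gamma_shape: 4.0, gamma_scale: 4.0}
    rate: {min: 0.4, central: 1.5, max: 2.6}
    stocks: {sediment_c: 140.0, biomass_c: 2.0, total_co2: 522.0}
    loss: {min: 0.25, max: 1.0}
simulation:
  iterations: 50000
  seed: 1
  percentiles: [0.05, 0.5, 0.95]
  gamma_shift: true
  aggregation: column_sum
economics: {scc_low: 7.0, scc_central: 41.0, scc_high: 81.0}
references:
  - {name: deforestation, value: 5.5}
  - {name: shelf_sink, value: 1.26}
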