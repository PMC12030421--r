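# Surrogate rice growth model constants (version 1).
# None of these are field-calibrated cultivar coefficients; they are chosen so
# the model is deterministic, smooth and monotone in the management parameters,
# with a nitrogen yield response that plateaus above ~210 kg/ha and canopies
# dense enough (peak LAI > 7 at high N) to exercise NDVI saturation.
version: 1
phenology:
  base_temp: 10.0          # deg C, GDD base temperature
  gdd_at_stage:            # cumulative deg C d after sowing
    tilling: 320.0
    jointing: 650.0
    booting: 980.0
    flowering: 1300.0
    maturity: 1750.0
canopy:
  lai_pot: 17.0            # potential LAI ceiling before density/N scaling
  k_seed: 20.0             # kg/ha half-saturation of the ceiling density response
  k_n: 150.0               # kg/ha half-saturation of Michaelis-Menten N ceiling
  r_growth: 0.006          # per deg C d, logistic canopy relative growth rate
  lai_init_per_seed: 0.0008 # initial LAI at sowing per kg/ha seed (early
                            # canopy scales with plant density)
  senescence_rate: 0.0011  # per deg C d after flowering
nitrogen:
  soil_n: 60.0             # kg/ha mineralizable soil N pool (single scalar)
  uptake_max: 0.65         # kg N/ha per day per unit LAI, potential uptake
  k_uptake: 100.0          # kg/ha half-saturation of pool-limited uptake
  n_split: [0.5, 0.5]      # fertilizer fractions at pre-planting and jointing
assimilate:
  rue: 1.2                 # g dry matter per MJ intercepted
  k_ext: 0.6               # canopy light extinction coefficient
  harvest_index: 0.45
  k_yield_n: 55.0          # kg/ha scale of saturating yield N response
  biomass_to_kg_ha: 10.0   # g/m2 -> kg/ha
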