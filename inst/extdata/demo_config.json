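{
  "seed": 1,
  "seed_model": {
    "f_H": 0.1,
    "rho_ratio": 1.5,
    "C_H": 300,
    "C_C": 2
  },
  "limit": {
    "jurisdiction": "Korea",
    "product": "seed",
    "limit": 5
  },
  "extraction": {
    "seed_mass_g": 5,
    "oil_type": "soybean",
    "oil_fraction": 0.4,
    "temperature_C": 50,
    "duration_min": 30,
    "wash_water_ratio": 4,
    "wash_cycles": 4,
    "reuse_water": false,
    "k_per_min": 0.2,
    "oil_absorption_g_per_g": 0.025,
    "oil_phase_split": 0.1,
    "wash_efficiency": 0.8
  },
  "quant": {
    "extract_volume_mL": 20,
    "dilution_factor": 1,
    "calibration": {
      "top_level_mg_L": 50,
      "n_levels": 8,
      "dilution_factor": 2
    }
  },
  "verbosity": 1
}
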