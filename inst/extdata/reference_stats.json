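{
  "version": "1.0",
  "sd_bond": 0.02,
  "sd_angle": 2.5,
  "sd_omega": 6,
  "sd_planarity": 15,
  "sd_improper": 3,
  "improper_ideal": 123.09609073,
  "rama_mean": 1,
  "rama_sd": 0.02,
  "backbone_mean": -9.11209253,
  "backbone_sd": 0.11871973,
  "packing_mean": 6.97698413,
  "packing_sd": 0.75044578,
  "rotamer_mean": 2.05864147,
  "rotamer_sd": 2.99079316,
  "inout_hydro_mean": 0.63756431,
  "inout_hydro_sd": 0.21233123,
  "inout_polar_mean": 0.66788179,
  "inout_polar_sd": 0.18790093
}
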