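{
  "config_version": "1.0",
  "comment": "Default single-compartment ChI model. Geometry, capacitance, leak conductance, maximal conductances, reversal potentials and resting-potential targets follow the experimental compartment description this model reimplements; gate kinetics are configuration (documented in the methods vignette) chosen to satisfy the qualitative channel constraints: IKr slow (bell-shaped tau, 50-400 ms, ~400 ms near rest), non-inactivating, activation midpoint between -60 and -30 mV; IA fast (tau <= 15 ms) with inactivation.",
  "geometry": { "diameter_um": 15, "length_um": 40, "cm_uF_cm2": 1 },
  "leak": { "g_mS_cm2": 0.09, "e_mV": null },
  "target_rmp_mV": -40,
  "holding_pA": 0,
  "temperature_C": 33,
  "dt_ms": 0.025,
  "channels": [
    {
      "name": "IA",
      "gbar_mS_cm2": 2.0,
      "e_rev_mV": -85,
      "activation": { "v_half_mV": -40, "slope_mV": 15, "tau_ms": 2, "power": 1 },
      "inactivation": { "v_half_mV": -70, "slope_mV": -7, "tau_ms": 15, "power": 1 }
    },
    {
      "name": "IKr",
      "gbar_mS_cm2": 0.5,
      "e_rev_mV": -85,
      "activation": {
        "v_half_mV": -30,
        "slope_mV": 3,
        "tau": { "tau_min_ms": 50, "tau_max_ms": 400, "v_peak_mV": -40, "width_mV": 15 },
        "power": 1
      },
      "inactivation": null
    }
  ],
  "d2": {
    "peak_pA": -20,
    "onset_latency_ms": 100,
    "rise_dur_ms": 150,
    "decay_dur_ms": 250,
    "decay_shape": "linear"
  }
}
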