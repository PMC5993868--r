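{
  "catalog_version": "1.0",
  "scenarios": {
    "fig4a": {
      "kind": "vclamp_family",
      "description": "Voltage-clamp current families: 20 mV steps from -100 mV.",
      "holding_mV": -100, "step_mV": 20, "n_steps": 8, "step_dur_ms": 500
    },
    "fig4b": {
      "kind": "trapezoid_channel_compare",
      "description": "Trapezoid response with leak and IKr and/or IA; undershoot requires IKr.",
      "peak_pA": 100, "ramp_up_ms": 4000, "plateau_ms": 4000,
      "ramp_down_ms": 4000, "pre_ms": 500, "post_ms": 3000,
      "channel_sets": [[], ["IA"], ["IKr"], ["IA", "IKr"]]
    },
    "fig4c": {
      "kind": "ramp_lag",
      "description": "Triangular ramp; IKr current-density extremum lags the input extremum.",
      "peak_pA": 100, "ramp_up_ms": 2000, "plateau_ms": 0,
      "ramp_down_ms": 2000, "pre_ms": 500, "post_ms": 3000
    },
    "fig4d": {
      "kind": "rmp_compare",
      "description": "Undershoot lost at hyperpolarized RMP (I_h block), restored with depolarization.",
      "peak_pA": 100, "ramp_up_ms": 4000, "plateau_ms": 4000,
      "ramp_down_ms": 4000, "pre_ms": 500, "post_ms": 3000,
      "blocked_rmp_mV": -76
    },
    "fig4e": {
      "kind": "sine_amplitude_series",
      "description": "Short sine input; trough amplitude scales with input amplitude, latency does not.",
      "amplitudes_pA": [25, 50, 75, 100], "freq_Hz": 2, "duration_ms": 500,
      "half": true, "pre_ms": 500, "post_ms": 2500
    },
    "fig4f": {
      "kind": "d2_combination",
      "description": "D2 current and IKr hyperpolarization, separate and combined, after a stimulus at time zero.",
      "excit_peak_pA": 100, "excit_rise_ms": 200, "excit_plateau_ms": 300,
      "excit_fall_ms": 200, "pre_ms": 500, "post_ms": 2500,
      "d2_onset_ms": 300, "d2_decay_ms": 900, "d2_scale": 1.0
    },
    "fig4g": {
      "kind": "d2_timing",
      "description": "Input flanking a DA burst: D2 timed at pause onset suppresses the rebound, not the trough; 100% vs 25% D2.",
      "excit_peak_pA": 100, "excit_rise_ms": 200, "excit_plateau_ms": 300,
      "excit_fall_ms": 200, "pre_ms": 500,
      "rebound_peak_pA": 60, "rebound_rise_ms": 150, "rebound_plateau_ms": 200,
      "rebound_fall_ms": 150, "rebound_onset_ms": 1800,
      "d2_onset_ms": 1700, "d2_decay_ms": 700,
      "d2_scales": [1.0, 0.25, 0.0],
      "post_ms": 2500, "learning_scale": 1.0
    },
    "fig4h": {
      "kind": "learning_series",
      "description": "Enhanced excitatory input after learning deepens the undershoot monotonically.",
      "base": "fig4g", "learning_scales": [1.0, 1.5, 2.0], "d2_scale": 1.0
    },
    "s2a_mimic": {
      "kind": "undershoot_mimic",
      "description": "Negative current (-13.6 pA for 200 MOhm, 2.72 mV) shaped like the IKr hyperpolarization.",
      "r_in_MOhm": 200, "v_target_mV": 2.72, "pre_ms": 200, "post_ms": 1000
    },
    "discussion_25pA": {
      "kind": "small_withdrawal",
      "description": "Withdrawal of a 25 pA excitatory input still produces a detectable undershoot.",
      "peak_pA": 25, "ramp_up_ms": 1000, "plateau_ms": 1000,
      "ramp_down_ms": 100, "pre_ms": 500, "post_ms": 3000
    },
    "invivo_phase": {
      "kind": "invivo_phase",
      "description": "Synthetic slow-wave recording; SPN firing lags pChI firing by the configured phase.",
      "bin_ms": 20
    }
  }
}
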