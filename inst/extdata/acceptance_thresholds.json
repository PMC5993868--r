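{
  "thresholds_version": "1.0",
  "thresholds": [
    { "scenario": "fig4b", "metric": "undershoot_leak_IKr", "cmp": "ge", "value": 1.0 },
    { "scenario": "fig4b", "metric": "undershoot_leak_IA_IKr", "cmp": "ge", "value": 1.0 },
    { "scenario": "fig4b", "metric": "undershoot_leak", "cmp": "lt", "value": 0.2 },
    { "scenario": "fig4b", "metric": "undershoot_leak_IA", "cmp": "lt", "value": 0.2 },
    { "scenario": "fig4c", "metric": "lag_ms", "cmp": "gt", "value": 0 },
    { "scenario": "fig4d", "metric": "blocked_frac", "cmp": "le", "value": 0.2 },
    { "scenario": "fig4d", "metric": "restored_frac", "cmp": "ge", "value": 0.7 },
    { "scenario": "fig4e", "metric": "trough_monotone", "cmp": "ge", "value": 1 },
    { "scenario": "fig4e", "metric": "latency_range_ms", "cmp": "lt", "value": 20 },
    { "scenario": "fig4f", "metric": "combined_over_ikr", "cmp": "gt", "value": 1.0 },
    { "scenario": "fig4f", "metric": "prolong_ms", "cmp": "gt", "value": 0 },
    { "scenario": "fig4g", "metric": "trough_change_frac", "cmp": "lt", "value": 0.1 },
    { "scenario": "fig4g", "metric": "rebound_reduced", "cmp": "ge", "value": 1 },
    { "scenario": "fig4h", "metric": "trough_monotone", "cmp": "ge", "value": 1 },
    { "scenario": "s2a_mimic", "metric": "amplitude_pA", "cmp": "eq", "value": -13.6, "tol": 1e-9 },
    { "scenario": "discussion_25pA", "metric": "undershoot_mV", "cmp": "gt", "value": 0.5 },
    { "scenario": "invivo_phase", "metric": "lag_deg", "cmp": "abs_err_le", "target": 60, "value": 5 }
  ]
}
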