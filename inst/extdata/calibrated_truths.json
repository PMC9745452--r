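{
  "comment": "Generator calibration for the synthetic ex vivo experiment. Rate constants derive from published 90%-decay times via k = ln(10)/t90; depth plateaus are solved from the published 4-mm crossing anchors; LI-drop and diameter plateaus are assumed constants (not published). Steam-pop logistic parameters are synthetic: chosen as a realistic world, not measured.",
  "decay_times_s": {
    "li_drop":  {"40": {"10": 46.9, "30": 38.9, "50": 40.6},
                 "50": {"10": 28.8, "30": 24.5, "50": 30.7}},
    "depth":    {"40": {"10": 37.0, "30": 37.0, "50": 33.3},
                 "50": {"10": 28.3, "30": 12.4, "50": 22.5}},
    "diameter": {"40": {"10": 26.2, "30": 22.2, "50": 21.0},
                 "50": {"10": 23.7, "30": 11.9, "50": 22.2}}
  },
  "depth_4mm_anchor_s": {
    "40": {"10": 25.9, "30": 23.1, "50": 20.0},
    "50": {"10": 20.9, "30": 11.8, "50": 19.2}
  },
  "anchor_depth_mm": 4.0,
  "assumed_plateaus": {
    "li_drop": {"value": 120.0, "units": "ohm", "provenance": "assumed"},
    "diameter": {"value": 8.0, "units": "mm", "provenance": "assumed"}
  },
  "noise": {
    "li_drop_cv": 0.10,
    "depth_sd_mm": 0.3,
    "diameter_sd_mm": 0.3
  },
  "pop_model": {
    "40": {"intercept": -6.0, "slope": 0.06, "provenance": "synthetic"},
    "50": {"intercept": -5.0, "slope": 0.08, "provenance": "synthetic"}
  },
  "geometry_coupling": {"c_over_a": 0.5, "d_over_b": 0.8,
    "comment": "synthetic-only convention so volume is computable"}
}
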