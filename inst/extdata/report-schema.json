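{
  "title": "maldiscreen audit report",
  "required": ["software", "criteria", "calibration", "detections", "matches"],
  "detection_fields": ["sample_id", "polarity", "name", "species",
    "n_detected", "n_measured", "detected", "validated",
    "mean_mass_error_mda", "mean_score", "isobar_group"],
  "match_fields": ["well_id", "polarity", "name", "species",
    "mz_theoretical", "mz_observed", "mass_error_mda", "peak_height",
    "iso_fit_score", "blank_threshold", "pass_mass", "pass_sigma",
    "pass_blank", "passed_all"]
}
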