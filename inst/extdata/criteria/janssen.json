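{
  "trial_id": "JANSSEN",
  "unverified": true,
  "min_age_years": 60,
  "min_age_exclusive": false,
  "area_min_mm2": 2.5,
  "area_max_mm2": 20.0,
  "require_no_study_eye_cnv": true,
  "require_no_fellow_eye_cnv": true,
  "require_central_ga": true,
  "require_non_fovea_involving": true
}
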