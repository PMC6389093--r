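description: SYNTHETIC example classifier for TIA/minor stroke vs mimic. Coefficients
  are fabricated for demonstration and testing; NOT clinically derived or validated.
expected_mains: 50
expected_interactions: 12
intercept: -0.788
main_effects:
  unilateral_weakness: 1.534
  speech_disturbance: 1.116
  facial_droop: 1.595
  sensory_loss: 0.48
  visual_loss: 0.463
  gait_ataxia: 0.205
  hypertension_history: 0.375
  atrial_fibrillation: 0.463
  hyperlipidaemia: 0.205
  smoking: 0.098
  diplopia: -0.747
  vertigo: -1.099
  headache: -1.329
  confusion: -0.811
  seizure: -2.153
  syncope: -1.695
  amnesia: -1.034
  nausea: -1.558
  neck_pain: 0.244
  tinnitus: 0.15
  chest_pain: 0.036
  palpitations: 0.134
  dysphagia: 0.096
  drowsiness: 0.065
  limb_shaking: 0.158
  scintillating_scotoma: 0.106
  visual_aura: 0.187
  photophobia: 0.044
  phonophobia: 0.158
  facial_numbness: 0.221
  hand_clumsiness: 0.063
  word_finding_difficulty: 0.123
  dysarthria: 0.178
  hemianopia: 0.148
  monocular_blindness: 0.236
  hiccups: 0.115
  tremor: 0.156
  falls: -0.116
  incoordination: -0.144
  memory_gap: -0.056
  eye_pain: -0.186
  scalp_tenderness: -0.099
  jaw_claudication: -0.056
  fever: -0.118
  recent_head_injury: -0.133
  anticoagulated: -0.219
  prior_tia: -0.193
  prior_stroke: -0.049
  age_years: 0.004
  duration_minutes: 0.0008
interactions:
- features:
  - unilateral_weakness
  - speech_disturbance
  coef: 0.35
- features:
  - unilateral_weakness
  - facial_droop
  coef: 0.3
- features:
  - speech_disturbance
  - facial_droop
  coef: 0.25
- features:
  - unilateral_weakness
  - sensory_loss
  coef: 0.2
- features:
  - atrial_fibrillation
  - prior_tia
  coef: 0.18
- features:
  - hypertension_history
  - prior_stroke
  coef: 0.15
- features:
  - visual_loss
  - hemianopia
  coef: 0.22
- features:
  - sensory_loss
  - facial_numbness
  coef: 0.12
- features:
  - headache
  - nausea
  coef: -0.3
- features:
  - headache
  - photophobia
  coef: -0.35
- features:
  - vertigo
  - nausea
  coef: -0.2
- features:
  - confusion
  - amnesia
  coef: -0.15
codebook:
  age_years:
    type: field
    field: age_years
  duration_minutes:
    type: field
    field: duration_minutes
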