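# Template: per-stratum recurrent-stroke risk anchors.
# Fill each slot with cumulative risk estimates from the literature or local
# audit data. Within a stratum, risks must be non-decreasing in `days` and
# strictly below 1. At least one anchor per stratum is required; the fitted
# hazard is piecewise-constant between anchor horizons and zero beyond the
# last one.
LOW:
  - {days: 7, risk: ~}    # e.g. 7-day cumulative risk for ABCD2 0-3
  - {days: 90, risk: ~}
MODERATE:
  - {days: 7, risk: ~}
  - {days: 90, risk: ~}
HIGH:
  - {days: 7, risk: ~}
  - {days: 90, risk: ~}
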