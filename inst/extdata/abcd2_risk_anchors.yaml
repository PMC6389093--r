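# Cumulative recurrent-stroke risk anchors per ABCD2 risk stratum.
# Values follow the pooled ABCD2 validation literature (2-, 7-, and 90-day
# stroke risk by score group). Units using different local estimates should
# substitute their own anchors; `risk` is a cumulative probability by day
# `days` after symptom onset.
LOW:
  - {days: 2, risk: 0.010}
  - {days: 7, risk: 0.012}
  - {days: 90, risk: 0.031}
MODERATE:
  - {days: 2, risk: 0.041}
  - {days: 7, risk: 0.059}
  - {days: 90, risk: 0.098}
HIGH:
  - {days: 2, risk: 0.081}
  - {days: 7, risk: 0.117}
  - {days: 90, risk: 0.178}
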