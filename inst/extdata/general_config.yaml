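# General-population risk characterization for benzene: continuous (24 h)
# exposure, activity assumed similar to the study animals, compared with
# the EU ambient air limit. Assessment factors are illustrative.
pod_override: [9.6, 14.2]
adjustment: general
exposure:
  lower: 1.5     # ppb, EU ambient limit (5 ug/m3)
  upper: 1.5
afs:
  - {value: 2.5, rationale: interspecies_tk_td, note: interspecies TK/TD variability}
  - {value: 6,   rationale: duration,          note: 28-day study to chronic}
  - {value: 10,  rationale: intraspecies,      note: general population}
  - {value: 3,   rationale: severity,          note: severity of the effect}
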