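# Worker-scenario risk characterization for benzene, using the published
# BMCL50/BMCU50 PoD as an external input. Assessment factors follow the
# occupational opinion they illustrate and should not be seen as setting a
# precedent.
pod_override: [9.6, 14.2]
adjustment: worker
exposure:
  lower: 50      # ppb, long-term average European workplace range
  upper: 100
afs:
  - {value: 2.5, rationale: interspecies_tk_td, note: interspecies TK/TD variability}
  - {value: 6,   rationale: duration,          note: 28-day study to chronic}
  - {value: 5,   rationale: intraspecies,      note: worker population}
  - {value: 3,   rationale: severity,          note: severity of the effect}
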