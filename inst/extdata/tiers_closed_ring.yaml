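# Tier/domain configuration for the constricted closed planar ring model
# (A. aeolicus numbering: globe 8-109, hairpin 110-149, C-terminal motor
# domain from ~160). Ring order A..F (planar; no spiral polarity).
tiers:
  - name: CTD
    domains:
      - {label: CTD-A, chain: A, start: 160, end: 440}
      - {label: CTD-B, chain: B, start: 160, end: 440}
      - {label: CTD-C, chain: C, start: 160, end: 440}
      - {label: CTD-D, chain: D, start: 160, end: 440}
      - {label: CTD-E, chain: E, start: 160, end: 440}
      - {label: CTD-F, chain: F, start: 160, end: 440}
  - name: NTD-globe
    domains:
      - {label: NTD-A, chain: A, start: 8, end: 109}
      - {label: NTD-B, chain: B, start: 8, end: 109}
      - {label: NTD-C, chain: C, start: 8, end: 109}
      - {label: NTD-D, chain: D, start: 8, end: 109}
      - {label: NTD-E, chain: E, start: 8, end: 109}
      - {label: NTD-F, chain: F, start: 8, end: 109}
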