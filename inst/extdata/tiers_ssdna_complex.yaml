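# Tier/domain configuration for the translocating ssDNA-bound helicase
# model (G. stearothermophilus numbering: globe 1-112, hairpin 113-151,
# C-terminal motor domain from ~185). Spiral order bottom -> top.
tiers:
  - name: CTD
    domains:
      - {label: CTD-A, chain: A, start: 185, end: 454}
      - {label: CTD-F, chain: F, start: 185, end: 454}
      - {label: CTD-E, chain: E, start: 185, end: 454}
      - {label: CTD-D, chain: D, start: 185, end: 454}
      - {label: CTD-C, chain: C, start: 185, end: 454}
      - {label: CTD-B, chain: B, start: 185, end: 454}
  - name: NTD-globe
    domains:
      - {label: NTD-A, chain: A, start: 1, end: 112}
      - {label: NTD-F, chain: F, start: 1, end: 112}
      - {label: NTD-E, chain: E, start: 1, end: 112}
      - {label: NTD-D, chain: D, start: 1, end: 112}
      - {label: NTD-C, chain: C, start: 1, end: 112}
      - {label: NTD-B, chain: B, start: 1, end: 112}
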