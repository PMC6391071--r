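# Tier/domain configuration for the open-spiral helicase-loader complex
# model (six helicase chains A-F, five loader chains V-Z).
#
# Spiral order is bottom -> top: chain A at the bottom of the staircase,
# chain B at the top; the breached interface is the wrap-around pair (B, A).
#
# Two conventions for the N-terminal globe interval circulate (31-113 from
# the plane-fit protocol; 32-123 as the "head" with a 124-173 hairpin
# "tail"); both are provided, select the profile explicitly.
tiers:
  - name: CTD
    domains:
      - {label: CTD-A, chain: A, start: 203, end: 471}
      - {label: CTD-F, chain: F, start: 203, end: 471}
      - {label: CTD-E, chain: E, start: 203, end: 471}
      - {label: CTD-D, chain: D, start: 203, end: 471}
      - {label: CTD-C, chain: C, start: 203, end: 471}
      - {label: CTD-B, chain: B, start: 203, end: 471}
  - name: NTD-globe
    domains:
      - {label: NTD-A, chain: A, start: 31, end: 113}
      - {label: NTD-F, chain: F, start: 31, end: 113}
      - {label: NTD-E, chain: E, start: 31, end: 113}
      - {label: NTD-D, chain: D, start: 31, end: 113}
      - {label: NTD-C, chain: C, start: 31, end: 113}
      - {label: NTD-B, chain: B, start: 31, end: 113}
  - name: NTD-head
    domains:
      - {label: head-A, chain: A, start: 32, end: 123}
      - {label: head-F, chain: F, start: 32, end: 123}
      - {label: head-E, chain: E, start: 32, end: 123}
      - {label: head-D, chain: D, start: 32, end: 123}
      - {label: head-C, chain: C, start: 32, end: 123}
      - {label: head-B, chain: B, start: 32, end: 123}
  - name: NTD-tail
    domains:
      - {label: tail-A, chain: A, start: 124, end: 173}
      - {label: tail-F, chain: F, start: 124, end: 173}
      - {label: tail-E, chain: E, start: 124, end: 173}
      - {label: tail-D, chain: D, start: 124, end: 173}
      - {label: tail-C, chain: C, start: 124, end: 173}
      - {label: tail-B, chain: B, start: 124, end: 173}
  - name: loader
    domains:
      - {label: P1-Z, chain: Z, start: 109, end: 233}
      - {label: P2-Y, chain: Y, start: 109, end: 233}
      - {label: P3-X, chain: X, start: 109, end: 233}
      - {label: P4-W, chain: W, start: 109, end: 233}
      - {label: P5-V, chain: V, start: 109, end: 233}
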