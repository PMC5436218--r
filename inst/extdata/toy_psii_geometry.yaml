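slab:
  z_lo: -2.0
  z_hi: 2.0
monomers:
- id: 1
  cavity:
    poly:
    - - -2.0
      - -2.0
    - - 2.0
      - -2.0
    - - 2.0
      - 2.0
    - - -2.0
      - 2.0
    z_lo: -2.0
    z_hi: 2.0
  site:
    center:
    - 0.0
    - 1.0
    - 0.8
    radius: 0.6
  channels:
  - label: I
    interior:
      poly:
      - - -0.5
        - -4.0
      - - 0.5
        - -4.0
      - - 0.5
        - -2.0
      - - -0.5
        - -2.0
      z_lo: -1.0
      z_hi: 1.0
    inner_gate:
      point:
      - 0.0
      - -2.0
      - 0.0
      normal:
      - 0.0
      - 1.0
      - 0.0
    outer_gate:
      point:
      - 0.0
      - -4.0
      - 0.0
      normal:
      - 0.0
      - -1.0
      - 0.0
  - label: II
    interior:
      poly:
      - - -0.5
        - 2.0
      - - 0.5
        - 2.0
      - - 0.5
        - 4.0
      - - -0.5
        - 4.0
      z_lo: -0.6
      z_hi: 0.6
    inner_gate:
      point:
      - 0.0
      - 2.0
      - 0.0
      normal:
      - 0.0
      - -1.0
      - 0.0
    outer_gate:
      point:
      - 0.0
      - 4.0
      - 0.0
      normal:
      - 0.0
      - 1.0
      - 0.0
  - label: III
    interior:
      poly:
      - - 2.0
        - -0.55
      - - 4.0
        - -0.55
      - - 4.0
        - 0.55
      - - 2.0
        - 0.55
      z_lo: -1.0
      z_hi: 1.0
    inner_gate:
      point:
      - 2.0
      - 0.0
      - 0.0
      normal:
      - -1.0
      - 0.0
      - 0.0
    outer_gate:
      point:
      - 4.0
      - 0.0
      - 0.0
      normal:
      - 1.0
      - 0.0
      - 0.0
footprint:
  poly:
  - - -4.0
    - -4.0
  - - 4.0
    - -4.0
  - - 4.0
    - 4.0
  - - -4.0
    - 4.0
  z_lo: -2.0
  z_hi: 2.0
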