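conditions:
  - name: Empowerment
    kind: crisp
    description: Empowerment model of community engagement evident
  - name: Design
    kind: crisp
    description: Community consulted on intervention design
  - name: Lay-led
    kind: crisp
    description: Intervention led by members of the community
  - name: Quality
    kind: fuzzy
    description: High-quality engagement (customisable, personal contact, counselling, trained staff)
  - name: Intensity
    kind: fuzzy
    description: Frequent contact in the critical pre-/post-partum period
outcome:
  name: Highly effective intervention
  calibrated: true
raw_effect: Effect size (raw odds ratio)
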