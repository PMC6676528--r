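# Two successive whole-genome doublings, observed at the present.
# Component means under the decay model: ~0.64 (100 My), ~0.84 (40 My).
type: schedule
M1: 10000
events:
  - kind: wgd
    ploidy: 2
    u: [0.0, 0.7, 0.3]
    time: 100
  - kind: wgd
    ploidy: 2
    u: [0.0, 0.5, 0.5]
    time: 40
  - kind: observation
    time: 0
decay:
  C: 1.0
  lambda: 0.0045
sd_model:
  intercept: 0.12
  slope: -0.10
replicates: 1
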