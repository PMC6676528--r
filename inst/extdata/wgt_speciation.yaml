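# An early whole-genome tripling shared by two sister species, then
# speciation; no post-speciation WGDs (petunia/pepper-like structure).
type: scenario
M1: 8000
shared:
  - kind: wgd
    ploidy: 3
    u: [0.0, 0.76, 0.2, 0.04]
    time: 120
  - kind: speciation
    u: [0.0, 0.3, 0.7]
    time: 36
branch_a:
  - kind: observation
    time: 0
branch_b:
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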