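# Tomato-versus-outgroup-like structure: an ancient shared tripling, a
# remote speciation, and one additional WGD in branch A only (so ortholog
# counts against A are amplified by F_A = 1 + u2 = 1.75).
type: scenario
M1: 6000
shared:
  - kind: wgd
    ploidy: 3
    u: [0.0, 0.79, 0.18, 0.03]
    time: 130
  - kind: speciation
    u: [0.0, 0.4, 0.6]
    time: 115
branch_a:
  - kind: wgd
    ploidy: 2
    u: [0.0, 0.25, 0.75]
    time: 71
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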