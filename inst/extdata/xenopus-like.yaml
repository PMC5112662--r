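seed: 1
times:
  root: 120.0
  dup_start: 118.0
  dup_end: 90.0
  speciation: 60.0
  allo: 40.0
  losses: 35.0
  conversion: 2.0
rates:
  mu: 0.006
  intron_mult: 1.5
  kappa: 1.0
template:
  leader: 19.0
  'N': 107.0
  IgC: 93.0
  TM: 24.0
  cyt: 40.0
  introns:
  - 250
  - 250
  - 250
  - 250
  intergenic: 400
omega:
  bg: 0.2
  sel: 2.0
  windows:
    start:
    - 26.0
    - 37.0
    - 47.0
    - 77.0
    - 91.0
    end:
    - 35.0
    - 44.0
    - 55.0
    - 87.0
    - 101.0
subgroups:
  group1:
    'n': 20.0
    inhibitory: g1_01
    activating: g1_02
  group2:
    'n': 18.0
    inhibitory: g2_01
    activating:
    - g2_02
    - g2_03
extra_itim:
- g1_10
- g2_10
gpi:
- g1_15
- g2_15
s_retained:
- g1_05
- g2_01
- g2_07
- g2_15
pseudogenes:
  base:
  - g1_12
  - g2_09
  species:
  - A
  - B
  tag:
  - none
  - L
  mode:
  - stop
  - splice_donor
conversion_tract: ~
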