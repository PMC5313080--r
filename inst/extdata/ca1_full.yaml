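cell_types:
- name: pyr
  count: 311500.0
  layer: SP
  is_principal: yes
- name: pvb
  count: 5530.0
  layer: SP
  is_principal: no
- name: cck
  count: 3600.0
  layer: SP
  is_principal: no
- name: sca
  count: 400.0
  layer: SR
  is_principal: no
- name: axo
  count: 1470.0
  layer: SP
  is_principal: no
- name: bis
  count: 2210.0
  layer: SP
  is_principal: no
- name: olm
  count: 1640.0
  layer: SO
  is_principal: no
- name: ivy
  count: 8810.0
  layer: SP
  is_principal: no
- name: ngf
  count: 3580.0
  layer: SLM
  is_principal: no
afferents:
- name: ca3
  count: 204700.0
  layer: SR
- name: ec3
  count: 250000.0
  layer: SLM
geometry:
  longitudinal_um: 15000.0
  transverse_um: 1000.0
  layer_bounds:
    SO:
    - 0.0
    - 100.0
    SP:
    - 100.0
    - 130.0
    SR:
    - 130.0
    - 350.0
    SLM:
    - 350.0
    - 450.0
budgets:
  axo:
    pyr: 1.12e+07
  bis:
    axo: 235000.0
    bis: 354000.0
    cck: 576000.0
    ivy: 264000.0
    olm: 640000.0
    pyr: 3.12e+07
    pvb: 885000.0
    sca: 68000.0
  cck:
    axo: 141000.0
    bis: 212000.0
    cck: 979000.0
    ivy: 564000.0
    olm: 262000.0
    pyr: 3.24e+07
    pvb: 531000.0
    sca: 83200.0
  ivy:
    axo: 353000.0
    bis: 530000.0
    cck: 3420000.0
    ivy: 2110000.0
    ngf: 1000000.0
    olm: 2230000.0
    pyr: 1.28e+08
    pvb: 1330000.0
    sca: 408000.0
  ngf:
    ngf: 609000.0
    pyr: 4.36e+07
  olm:
    axo: 118000.0
    bis: 177000.0
    cck: 1440000.0
    ngf: 465000.0
    olm: 98400.0
    pyr: 2.49e+07
    pvb: 442000.0
    sca: 160000.0
  pyr:
    axo: 719000.0
    bis: 2430000.0
    ivy: 238000.0
    olm: 1.17e+07
    pyr: 6.14e+07
    pvb: 7030000.0
    sca: 126000.0
  pvb:
    axo: 57300.0
    bis: 86200.0
    cck: 137000.0
    ivy: 70500.0
    pyr: 5.83e+07
    pvb: 216000.0
    sca: 9600.0
  sca:
    axo: 8820.0
    bis: 13300.0
    cck: 130000.0
    ivy: 106000.0
    olm: 19700.0
    pyr: 3740000.0
    pvb: 33200.0
    sca: 14400.0
  ca3:
    axo: 1.23e+07
    bis: 2.56e+07
    cck: 1.44e+07
    ivy: 3.39e+07
    pyr: 3.73e+09
    pvb: 6.69e+07
    sca: 1550000.0
  ec3:
    axo: 1430000.0
    bis: 1910000.0
    cck: 4020000.0
    ngf: 3750000.0
    pyr: 8.09e+08
    sca: 458000.0
syn_per_conn:
  axo:
    pyr: 6.0
  bis:
    axo: 3.0
    bis: 3.0
    cck: 3.0
    ivy: 3.0
    olm: 3.0
    pyr: 10.0
    pvb: 3.0
    sca: 3.0
  cck:
    axo: 3.0
    bis: 3.0
    cck: 3.0
    ivy: 3.0
    olm: 3.0
    pyr: 8.0
    pvb: 3.0
    sca: 3.0
  ivy:
    axo: 3.0
    bis: 3.0
    cck: 3.0
    ivy: 3.0
    ngf: 3.0
    olm: 3.0
    pyr: 9.0
    pvb: 3.0
    sca: 3.0
  ngf:
    ngf: 3.0
    pyr: 7.0
  olm:
    axo: 3.0
    bis: 3.0
    cck: 3.0
    ngf: 3.0
    olm: 3.0
    pyr: 10.0
    pvb: 3.0
    sca: 3.0
  pyr:
    axo: 1.0
    bis: 1.0
    ivy: 1.0
    olm: 1.0
    pyr: 1.0
    pvb: 1.0
    sca: 1.0
  pvb:
    axo: 3.0
    bis: 3.0
    cck: 3.0
    ivy: 3.0
    pyr: 10.0
    pvb: 3.0
    sca: 3.0
  sca:
    axo: 3.0
    bis: 3.0
    cck: 3.0
    ivy: 3.0
    olm: 3.0
    pyr: 5.0
    pvb: 3.0
    sca: 3.0
  ca3:
    axo: 1.0
    bis: 1.0
    cck: 1.0
    ivy: 1.0
    pyr: 1.0
    pvb: 1.0
    sca: 1.0
  ec3:
    axo: 1.0
    bis: 1.0
    cck: 1.0
    ngf: 1.0
    pyr: 1.0
    sca: 1.0
weights:
  axo:
    pyr: 0.4
  bis:
    axo: 0.1
    bis: 0.1
    cck: 0.1
    ivy: 0.1
    olm: 0.1
    pyr: 0.4
    pvb: 0.1
    sca: 0.1
  cck:
    axo: 0.1
    bis: 0.1
    cck: 0.1
    ivy: 0.1
    olm: 0.1
    pyr: 0.4
    pvb: 0.1
    sca: 0.1
  ivy:
    axo: 0.1
    bis: 0.1
    cck: 0.1
    ivy: 0.1
    ngf: 0.1
    olm: 0.1
    pyr: 0.4
    pvb: 0.1
    sca: 0.1
  ngf:
    ngf: 0.1
    pyr: 0.4
  olm:
    axo: 0.1
    bis: 0.1
    cck: 0.1
    ngf: 0.1
    olm: 0.1
    pyr: 0.4
    pvb: 0.1
    sca: 0.1
  pyr:
    axo: 0.18
    bis: 0.18
    ivy: 0.1
    olm: 0.02
    pyr: 0.35
    pvb: 0.18
    sca: 0.12
  pvb:
    axo: 0.1
    bis: 0.1
    cck: 0.1
    ivy: 0.1
    pyr: 0.4
    pvb: 0.1
    sca: 0.1
  sca:
    axo: 0.1
    bis: 0.1
    cck: 0.1
    ivy: 0.1
    olm: 0.1
    pyr: 0.4
    pvb: 0.1
    sca: 0.1
  ca3:
    axo: 0.04
    bis: 0.04
    cck: 0.25
    ivy: 0.3
    pyr: 0.095
    pvb: 0.04
    sca: 0.15
  ec3:
    axo: 0.04
    bis: 0.04
    cck: 0.25
    ngf: 0.6
    pyr: 0.095
    sca: 0.15
axonal_profiles:
- name: pyr
  mean_um: 0.0
  sd_um: 1000.0
  extent_um: 2000.0
  bin_um: 100.0
- name: pvb
  mean_um: 0.0
  sd_um: 300.0
  extent_um: 800.0
  bin_um: 100.0
- name: cck
  mean_um: 0.0
  sd_um: 300.0
  extent_um: 800.0
  bin_um: 100.0
- name: sca
  mean_um: 0.0
  sd_um: 300.0
  extent_um: 800.0
  bin_um: 100.0
- name: axo
  mean_um: 0.0
  sd_um: 300.0
  extent_um: 800.0
  bin_um: 100.0
- name: bis
  mean_um: 0.0
  sd_um: 300.0
  extent_um: 800.0
  bin_um: 100.0
- name: olm
  mean_um: 0.0
  sd_um: 300.0
  extent_um: 800.0
  bin_um: 100.0
- name: ivy
  mean_um: 0.0
  sd_um: 300.0
  extent_um: 800.0
  bin_um: 100.0
- name: ngf
  mean_um: 0.0
  sd_um: 200.0
  extent_um: 500.0
  bin_um: 100.0
- name: ca3
  mean_um: 0.0
  sd_um: 3000.0
  extent_um: 10000.0
  bin_um: 100.0
- name: ec3
  mean_um: 0.0
  sd_um: 3000.0
  extent_um: 10000.0
  bin_um: 100.0
zones:
  axo->pyr:
  - AIS
  pvb->pyr:
  - soma
  - proximal_dendrite_SR
  cck->pyr:
  - soma
  - proximal_dendrite_SR
  bis->pyr:
  - basal_dendrite
  - proximal_dendrite_SR
  ivy->pyr:
  - basal_dendrite
  - proximal_dendrite_SR
  sca->pyr:
  - proximal_dendrite_SR
  olm->pyr:
  - distal_dendrite_SLM
  ngf->pyr:
  - distal_dendrite_SLM
  pyr->pyr:
  - basal_dendrite
  ca3->pyr:
  - proximal_dendrite_SR
  - basal_dendrite
  ec3->pyr:
  - distal_dendrite_SLM
  default:
  - soma
  - proximal_dendrite_SR
neuron_params:
- name: pyr
  EL: -63.0
  R: 62.2
  taum: 4.8
  VT: -45.45
  DeltaT: 2.0
  Vreset: -63.0
  Vpeak: -20.45
  tref: 2.0
  b: 100.0
  tauw: 100.0
- name: pvb
  EL: -65.0
  R: 52.0
  taum: 6.9
  VT: -46.987
  DeltaT: 2.413
  Vreset: -65.0
  Vpeak: -21.987
  tref: 1.0
  b: 0.0
  tauw: 50.0
- name: cck
  EL: -70.6
  R: 211.0
  taum: 22.6
  VT: -55.154
  DeltaT: 2.786
  Vreset: -70.6
  Vpeak: -30.154
  tref: 2.0
  b: 10.0
  tauw: 100.0
- name: sca
  EL: -70.5
  R: 272.4
  taum: 24.4
  VT: -57.001
  DeltaT: 2.603
  Vreset: -70.5
  Vpeak: -32.001
  tref: 2.0
  b: 10.0
  tauw: 100.0
- name: axo
  EL: -65.0
  R: 52.0
  taum: 7.0
  VT: -52.081
  DeltaT: 2.519
  Vreset: -65.0
  Vpeak: -27.081
  tref: 1.0
  b: 0.0
  tauw: 50.0
- name: bis
  EL: -67.0
  R: 98.7
  taum: 14.7
  VT: -31.878
  DeltaT: 0.577
  Vreset: -67.0
  Vpeak: -6.878
  tref: 1.0
  b: 0.0
  tauw: 50.0
- name: olm
  EL: -71.5
  R: 343.8
  taum: 22.4
  VT: -52.31
  DeltaT: 2.0
  Vreset: -71.5
  Vpeak: -27.31
  tref: 2.0
  b: 15.0
  tauw: 150.0
- name: ivy
  EL: -60.0
  R: 100.0
  taum: 21.1
  VT: -41.359
  DeltaT: 2.641
  Vreset: -60.0
  Vpeak: -16.359
  tref: 2.0
  b: 10.0
  tauw: 100.0
- name: ngf
  EL: -60.0
  R: 100.0
  taum: 21.1
  VT: -40.564
  DeltaT: 2.436
  Vreset: -60.0
  Vpeak: -15.564
  tref: 2.0
  b: 10.0
  tauw: 100.0
channels:
- name: AMPA
  tau1: 0.5
  tau2: 3.0
  erev: 0.0
- name: GABAA
  tau1: 0.3
  tau2: 8.0
  erev: -60.0
- name: GABAA_NGF
  tau1: 1.0
  tau2: 11.0
  erev: -60.0
- name: GABAB
  tau1: 50.0
  tau2: 200.0
  erev: -90.0
channel_of:
  pyr: AMPA
  ca3: AMPA
  ec3: AMPA
  pvb: GABAA
  axo: GABAA
  bis: GABAA
  cck: GABAA
  sca: GABAA
  olm: GABAA
  ivy: GABAA
  ngf: GABAA_NGF
gabab:
  channel: GABAB
  g_ratio: 1.4
  reference_mv: -63.0
  targets:
  - pyr
  - ngf
delay:
  base_ms: 0.5
  velocity_um_per_ms: 300.0
stim:
  rate_hz: 0.65
electrode:
  longitudinal_um: 200.0
  transverse_um: 500.0
  height_um: 120.0
seed: 1.0
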