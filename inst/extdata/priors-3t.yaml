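# Versioned metabolite/water priors for water-referenced quantification at 3 T.
# Relaxation times and the tissue water concentration are literature-informed
# stand-in values for brain at 3 T; replace with site-measured values where
# available. linewidth_hz is the rendered line FWHM used by the simulator;
# water is rendered at the same linewidth as the metabolites so that finite
# integration windows attenuate metabolite and water areas identically (the
# attenuation cancels in the area ratio).
version: 1
field_ppm_hz: 127.728
water:
  ppm: 4.7
  n_protons: 2
  t1_ms: 1200
  t2_ms: 80
  cw_mM: 39412.1   # 55510 mM x 0.71 tissue water fraction
  linewidth_hz: 5
metabolites:
  - name: NAA
    ppm: 2.01
    n_protons: 3
    t1_ms: 1470
    t2_ms: 247
    linewidth_hz: 5
  - name: Cr
    ppm: 3.03
    n_protons: 3
    t1_ms: 1460
    t2_ms: 152
    linewidth_hz: 5
  - name: Cho
    ppm: 3.19
    n_protons: 9
    t1_ms: 1200
    t2_ms: 217
    linewidth_hz: 5
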