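# Bragg-curve position profiles for a passively scattered 150 MeV proton beam.
# yd_bar_keV_um pins the dose-averaged mean lineal energy at each position;
# the spectrum shape is a lognormal frequency distribution with the given
# coefficient of variation (the full measured spectrum shapes are not
# tabulated, only their yD is).
positions:
  - label: P36
    yd_bar_keV_um: 1.10
    cv: 0.8
    mean_proton_energy_MeV: 88.2
  - label: P80
    yd_bar_keV_um: 1.80
    cv: 0.8
    mean_proton_energy_MeV: 33.6
  - label: D20
    yd_bar_keV_um: 7.25
    cv: 0.8
    mean_proton_energy_MeV: 12.9
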