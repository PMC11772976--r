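position,d37_Gy,d10_Gy,t_half_h,t_half_se_h,yd_bar_keV_um,mean_proton_energy_MeV,ssb_per_Gy_Gbps,dsb_per_Gy_Gbps,ssb_over_dsb,dsb_frac_of_sb_pct,complex_frac_of_sb_pct
P36,3.0,5.2,2.65,0.36,1.10,88.2,291.66,9.51,29.7,3.3,0.48
P80,2.9,4.8,2.97,0.01,1.80,33.6,282.91,10.02,27.2,3.5,0.55
D20,1.6,3.4,4.40,0.17,7.25,12.9,260.54,11.62,21.4,4.5,0.88
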