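sample_id,yield_pct,swelling_pct,loaded_mg,loaded_eff_pct,released_max,released_eff_pct,k_h_per_sqrt_min,thickness_mm,D_printed_mm2_per_s
F1,86.1,238,12.6,57.87,10.24,80.99,4.13e-3,7.55,4.051e-6
F2,68.1,418,16.2,46.02,15.41,95.13,6.23e-3,5.67,5.199e-6
F3,77.9,409,13.3,55.76,12.05,90.80,5.48e-3,5.22,3.421e-6
F4,25.9,442,16.1,46.32,12.44,77.25,3.18e-3,2.07,0.181e-6
F5,25.2,957,17.9,40.23,17.65,98.42,5.77e-3,9.14,11.58e-6
F6,71.0,327,16.2,46.08,13.35,82.53,5.07e-3,4.91,2.582e-6
F7,38.6,292,10.5,65.15,9.03,86.39,5.44e-3,5.42,3.622e-6
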