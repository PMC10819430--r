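# Multi-temperature HSA-PFAS binding measurements: Stern-Volmer constants,
# bimolecular quenching constants, double-logarithmic binding constants and
# site numbers, and Van't Hoff thermodynamic parameters.
# Units: ksv L/mol; kq L/mol/s; kb L/mol; delta_h kJ/mol; delta_s J/mol/K; delta_g kJ/mol.
system,temperature_K,ksv,kq,kb,n_sites,delta_h_kj_mol,delta_s_j_mol_k,delta_g_kj_mol
HSA-PFNA,298,2.52e4,2.52e12,7.81e6,1.51,-278.25,-805.8,-39.32
HSA-PFNA,304,2.35e4,2.35e12,2.02e5,1.18,-278.25,-805.8,-30.86
HSA-PFNA,310,1.27e4,1.27e12,9.9e4,1.10,-278.25,-805.8,-29.65
HSA-HFPO-TA,298,1.78e4,1.78e12,3.7e6,1.49,412.15,1508.3,-37.47
HSA-HFPO-TA,304,1.95e4,1.95e12,8.54e7,1.78,412.15,1508.3,-46.16
HSA-HFPO-TA,310,1.98e4,1.98e12,2.31e9,2.09,412.15,1508.3,-55.57
HSA-PFOA,298,1.39e4,1.39e12,2.27e5,1.26,146.68,593.3,-30.55
HSA-PFOA,304,1.46e4,1.46e12,2.23e6,1.31,146.68,593.3,-32.85
HSA-PFOA,310,1.47e4,1.47e12,1.98e6,1.47,146.68,593.3,-37.67
HSA-PFO3DA,298,1.05e4,1.05e12,1.59e5,1.25,-106.57,-259.2,-29.67
HSA-PFO3DA,304,1.03e4,1.03e12,4.55e4,1.33,-106.57,-259.2,-27.11
HSA-PFO3DA,310,0.87e4,0.87e12,2.99e4,1.10,-106.57,-259.2,-26.56
HSA-PFHpA,298,0.69e4,0.69e12,4.53e3,0.96,324.98,1166.7,-20.86
HSA-PFHpA,304,0.53e4,0.53e12,5.35e5,1.42,324.98,1166.7,-33.34
HSA-PFHpA,310,0.32e4,0.32e12,7.47e5,1.50,324.98,1166.7,-34.86
HSA-DFSA,298,0.58e4,0.58e12,1.52e3,0.88,167.49,622.5,-18.15
HSA-DFSA,304,0.51e4,0.51e12,4.93e3,0.98,167.49,622.5,-21.49
HSA-DFSA,310,0.45e4,0.45e12,2.07e4,1.13,167.49,622.5,-25.62
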