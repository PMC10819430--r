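# MM/GBSA binding free energies and energy components for HSA-PFAS
# complexes (kcal/mol).
system,de_vdw,de_elec,dg_gb,dg_sa,dg_bind
HSA-HFPO-TA,-36.91,25.66,-18.10,-5.85,-35.20
HSA-PFO3DA,-21.38,-55.09,58.37,-4.36,-22.46
HSA-PFOA,-20.96,-7.20,4.38,-4.27,-28.04
HSA-PFHpA,-35.30,49.13,-29.24,-5.91,-21.31
HSA-PFNA,-28.64,-29.20,24.50,-5.49,-38.83
HSA-DFSA,-35.18,-20.45,43.33,-5.68,-17.98
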