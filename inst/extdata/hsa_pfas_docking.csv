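# Molecular docking binding energies of HSA-PFAS complexes (kcal/mol).
system,docking_energy_kcal_mol
HSA-PFNA,-8.2
HSA-HFPO-TA,-7.9
HSA-PFOA,-7.8
HSA-PFO3DA,-7.8
HSA-PFHpA,-7.1
HSA-DFSA,-7.3
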