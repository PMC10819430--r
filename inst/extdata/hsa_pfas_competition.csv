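# Site-marker competition data for HSA-PFAS binding: binding constant without
# the probe (kb_free) and with each pre-bound probe (kb_probe), plus the
# reported displacement percentage. The `consistent` flag marks rows whose
# reported phi matches (kb_free - kb_probe)/kb_free * 100 within 0.5
# percentage points; the HFPO-TA and PFOA rows carry internally inconsistent
# source values and are excluded from exact checks.
system,probe,kb_free,kb_probe,phi_pct_reported,consistent
HSA-PFNA,warfarin,7.81e6,1.33e5,98.3,TRUE
HSA-PFNA,ibuprofen,7.81e6,6.73e6,13.8,TRUE
HSA-PFNA,lidocaine,7.81e6,4.38e6,43.9,TRUE
HSA-HFPO-TA,warfarin,2.70e6,1.48e4,99.6,FALSE
HSA-HFPO-TA,ibuprofen,2.70e6,2.82e6,23.8,FALSE
HSA-HFPO-TA,lidocaine,2.70e6,2.39e6,35.3,FALSE
HSA-PFOA,warfarin,2.27e5,8.85e4,96.1,FALSE
HSA-PFOA,ibuprofen,2.27e5,2.26e5,40.8,FALSE
HSA-PFOA,lidocaine,2.27e5,2.09e5,8.1,FALSE
HSA-PFO3DA,warfarin,1.59e5,7.79e3,95.1,TRUE
HSA-PFO3DA,ibuprofen,1.59e5,1.18e5,25.8,TRUE
HSA-PFO3DA,lidocaine,1.59e5,1.40e5,11.8,TRUE
HSA-PFHpA,warfarin,4.53e3,4.98e1,98.9,TRUE
HSA-PFHpA,ibuprofen,4.53e3,2.60e3,42.7,TRUE
HSA-PFHpA,lidocaine,4.53e3,2.32e3,48.8,TRUE
HSA-DFSA,warfarin,1.52e3,1.02e2,93.3,TRUE
HSA-DFSA,ibuprofen,1.52e3,1.13e3,25.4,TRUE
HSA-DFSA,lidocaine,1.52e3,1.04e3,31.7,TRUE
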