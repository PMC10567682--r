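pop,CAL,OIA,PGR,FGO,TTZ,MAC
CAL,,,,,,
OIA,0.076,,,,,
PGR,0.031,0.084,,,,
FGO,0.066,0.074,0.021,,,
TTZ,0.034,0.067,0.004,0.016,,
MAC,0.040,0.050,0.026,0.031,0.019,
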