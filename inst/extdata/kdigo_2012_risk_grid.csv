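g_stage,a_stage,risk
G1,A1,low
G1,A2,moderate
G1,A3,high
G2,A1,low
G2,A2,moderate
G2,A3,high
G3a,A1,moderate
G3a,A2,high
G3a,A3,very_high
G3b,A1,high
G3b,A2,very_high
G3b,A3,very_high
G4,A1,very_high
G4,A2,very_high
G4,A3,very_high
G5,A1,very_high
G5,A2,very_high
G5,A3,very_high
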