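# Angle-triplet topology: angle label -> [first, vertex, last].
# Each angle is labelled by its vertex landmark; all triplets are
# same-side. Elbow and knee follow the shoulder-elbow-wrist and
# hip-knee-ankle chains; shoulder and hip use the torso chain; wrist and
# ankle (terminal joints) measure the chord back to the same-side hip.
ELR: [SHR, ELR, WR]
ELL: [SHL, ELL, WL]
KR:  [HR, KR, ANR]
KL:  [HL, KL, ANL]
HR:  [SHR, HR, KR]
HL:  [SHL, HL, KL]
SHR: [HR, SHR, ELR]
SHL: [HL, SHL, ELL]
WR:  [ELR, WR, HR]
WL:  [ELL, WL, HL]
ANR: [KR, ANR, HR]
ANL: [KL, ANL, HL]
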