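A: AGPST
B: DENQ
C: HKR
D: ILMV
E: FWY
F: C
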