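Dll4
Igfbp3
Unc5b
Gja4
Hey1
Mecom
Efnb2
Epas1
Vegfc
Cxcr4
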