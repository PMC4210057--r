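D01 D02
D01 D08
D02 D03
D02 D09
D03 D04
D03 D10
D04 D05
D04 D11
D05 D06
D05 D12
D06 D07
D06 D13
D07 D14
D08 D09
D08 D15
D09 D10
D09 D16
D10 D11
D10 D17
D11 D12
D11 D18
D12 D13
D12 D19
D13 D14
D13 D20
D14 D21
D15 D16
D15 D22
D16 D17
D16 D23
D17 D18
D17 D24
D18 D19
D18 D25
D19 D20
D19 D26
D20 D21
D20 D27
D21 D28
D22 D23
D22 D29
D23 D24
D23 D30
D24 D25
D24 D31
D25 D26
D25 D32
D26 D27
D26 D33
D27 D28
D27 D34
D28 D35
D29 D30
D29 D36
D30 D31
D30 D37
D31 D32
D31 D38
D32 D33
D32 D39
D33 D34
D33 D40
D34 D35
D34 D41
D36 D37
D37 D38
D38 D39
D39 D40
D40 D41
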