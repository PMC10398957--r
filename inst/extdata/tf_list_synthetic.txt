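NFIA
SOX9
SOX10
ST18
ID3
HOPX
G00399
G00522
G00862
G00241
G00379
G00340
G00735
G00438
G00686
G00237
G00700
G00853
G00123
G00494
G00493
G00371
G00260
G01096
G00290
G01103
G00171
G00826
G00965
G00546
G00153
G00283
G00917
G00348
G00845
G00613
G00598
G00547
G00637
G00792
G00095
G00421
G00667
G00243
G00411
G00581
G01011
G00426
G00402
G01134
G00467
G00169
G00287
G00415
G00056
G00312
G00712
G01145
G01143
G00335
G00927
G00330
G00525
G01048
G00576
G00790
G01049
G00387
G00669
G01025
G00913
G00727
G00045
G00693
G00277
G00688
G00375
G00073
G00933
G00697
G00090
G00906
G00158
G00410
G00267
G00148
G00016
G00930
G00911
G00429
G01037
G00156
G00831
G00041
G00787
G00173
G00692
G00657
G00458
G00360
G01098
G00077
G00211
G00646
G01038
G00265
G00944
G00994
G00814
G00777
G00069
G00726
G00986
G00018
G00236
G00621
DNG001
DNG002
DNG003
DNG004
DNG005
DNG006
DNG007
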