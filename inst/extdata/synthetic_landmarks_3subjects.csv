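subject_id,point,x,y
M20s_TE_0083,P1,0,14.6133881785809
M20s_TE_0083,P2,0,188.000790738683
M20s_TE_0083,P3,-72.2903969589758,91.454689225215
M20s_TE_0083,P4,72.2903969589758,91.454689225215
M20s_TE_0083,P5,-62.2543806270646,134.364067675645
M20s_TE_0083,P6,62.2543806270646,134.364067675645
M20s_TE_0083,P7,0,53.9089830810887
M20s_TE_0083,P8,0,113.185769774441
M20s_TE_0083,P9,-47.2292624096891,72.1454689225215
M20s_TE_0083,P10,47.2292624096891,72.1454689225215
M20s_TE_0083,P11,-16.5235193049088,72.1454689225215
M20s_TE_0083,P12,16.5235193049088,72.1454689225215
M20s_TE_0083,P13,-30.9815986967039,70
M20s_TE_0083,P14,30.9815986967039,70
M20s_TE_0083,P9p,-47.2292624096891,52.7522481254732
M20s_TE_0083,P10p,47.2292624096891,52.7522481254732
M20s_TE_0083,P11p,-16.5235193049088,52.7522481254732
M20s_TE_0083,P12p,16.5235193049088,52.7522481254732
M20s_TE_0083,P13p,-30.9815986967039,50.6067792029517
M20s_TE_0083,P14p,30.9815986967039,50.6067792029517
M20s_SY_0016,P1,0,-2.27233771270204
M20s_SY_0016,P2,0,187.518560652419
M20s_SY_0016,P3,-66.7839056696487,91.3670110277125
M20s_SY_0016,P4,66.7839056696487,91.3670110277125
M20s_SY_0016,P5,-53.5919679647459,134.101033083138
M20s_SY_0016,P6,53.5919679647459,134.101033083138
M20s_SY_0016,P7,0,53.9747417292156
M20s_SY_0016,P8,0,129.438798684258
M20s_SY_0016,P9,-48.2866573662343,72.1367011027713
M20s_SY_0016,P10,48.2866573662343,72.1367011027713
M20s_SY_0016,P11,-15.2648927244911,72.1367011027713
M20s_SY_0016,P12,15.2648927244911,72.1367011027713
M20s_SY_0016,P13,-28.6216738584209,70
M20s_SY_0016,P14,28.6216738584209,70
M20s_SY_0016,P9p,-48.2866573662343,57.413490911659
M20s_SY_0016,P10p,48.2866573662343,57.413490911659
M20s_SY_0016,P11p,-15.2648927244911,57.413490911659
M20s_SY_0016,P12p,15.2648927244911,57.413490911659
M20s_SY_0016,P13p,-28.6216738584209,55.2767898088877
M20s_SY_0016,P14p,28.6216738584209,55.2767898088877
M20s_SY_0013,P1,0,2.15210283300394
M20s_SY_0013,P2,0,178.320112308827
M20s_SY_0013,P3,-65.3261417896926,89.6945658743321
M20s_SY_0013,P4,65.3261417896926,89.6945658743321
M20s_SY_0013,P5,-58.8903848607236,129.083697622996
M20s_SY_0013,P6,58.8903848607236,129.083697622996
M20s_SY_0013,P7,0,55.2290755942509
M20s_SY_0013,P8,0,121.383382481963
M20s_SY_0013,P9,-46.3225118647873,71.9694565874332
M20s_SY_0013,P10,46.3225118647873,71.9694565874332
M20s_SY_0013,P11,-14.9316895519297,71.9694565874332
M20s_SY_0013,P12,14.9316895519297,71.9694565874332
M20s_SY_0013,P13,-27.9969179098682,70
M20s_SY_0013,P14,27.9969179098682,70
M20s_SY_0013,P9p,-46.3225118647873,54.5584941735533
M20s_SY_0013,P10p,46.3225118647873,54.5584941735533
M20s_SY_0013,P11p,-14.9316895519297,54.5584941735533
M20s_SY_0013,P12p,14.9316895519297,54.5584941735533
M20s_SY_0013,P13p,-27.9969179098682,52.5890375861201
M20s_SY_0013,P14p,27.9969179098682,52.5890375861201
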