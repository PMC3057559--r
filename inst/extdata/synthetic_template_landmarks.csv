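subject_id,point,x,y
template,P1,0,0
template,P2,0,180
template,P3,-70,90
template,P4,70,90
template,P5,-60,130
template,P6,60,130
template,P7,0,55
template,P8,0,120
template,P9,-47,72
template,P10,47,72
template,P11,-16,72
template,P12,16,72
template,P13,-30,70
template,P14,30,70
template,P9p,-47,55
template,P10p,47,55
template,P11p,-16,55
template,P12p,16,55
template,P13p,-30,53
template,P14p,30,53
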