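"subject_id","sex","age_group","type","height_m","weight_kg"
"M20s_TE_0083","M","20s","TE",1.82,85.1
"M20s_SY_0016","M","20s","SY",1.815,55.8
"M20s_SY_0013","M","20s","SY",1.716,70.5
"M20s_TE_0026","M","20s","TE",1.828,67.6
"M20s_SE_0020","M","20s","SE",1.77,75.7
"M20s_SY_0036","M","20s","SY",1.732,60.9
"M20s_TE_0033","M","20s","TE",1.752,93.3
"M20s_TE_0005","M","20s","TE",1.635,62.8
"M20s_SY_0056","M","20s","SY",1.69,61.4
"M20s_TE_0059","M","20s","TE",1.772,69.3
"M20s_TE_0022","M","20s","TE",1.791,80.7
"M20s_SE_0026","M","20s","SE",1.668,59.4
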