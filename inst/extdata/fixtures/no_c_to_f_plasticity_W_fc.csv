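"unit","f1","f2","f3","f4","f5","f6","f7","f8","f9","f10","f11","f12"
"c1",0.132677146621,0.134837833018,0.733806315604,0.130468803377,0.154390507714,0.160723432737,0.364484012478,0.149470432681,0.355703496593,0.179860452999,0.150695174667,0.149263069999
"c2",0.137556517804,0.138067883445,0.710841255474,0.14341084708,0.158703851699,0.172520243652,0.376659555564,0.15575608995,0.364627313228,0.184870325498,0.154176297899,0.155468740983
"c3",0.26917953678,0.274602518405,0.361008562727,0.265843936548,0.279572667907,0.275455885007,0.321151304134,0.267045580585,0.324855573419,0.269854319906,0.268098941863,0.269105535506
"c4",0.247488417691,0.255637289285,0.436896062436,0.241522795898,0.241417731797,0.25661575584,0.354523231909,0.254053789566,0.351100769736,0.253773872176,0.250024789881,0.244209106168
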