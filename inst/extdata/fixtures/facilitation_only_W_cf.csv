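"unit","c1","c2","c3","c4"
"f1",0.499575637304,0.49915703156,0.503491068895,0.497758158145
"f2",0.50641793965,0.498061408208,0.496256077181,0.499204977856
"f3",0.483785925338,0.517252341355,0.498855215723,0.499544460037
"f4",0.515586085744,0.495044655662,0.502529580275,0.486380301859
"f5",0.5063070579,0.495610953985,0.510615798431,0.487128783591
"f6",0.503486791423,0.499403426869,0.510638871285,0.486153485257
"f7",0.509630230759,0.488234404095,0.497176863589,0.504697296275
"f8",0.507564730026,0.506905282282,0.489006849762,0.496283568652
"f9",0.498935092656,0.508062965104,0.501579979249,0.491277234587
"f10",0.521737500575,0.489950171036,0.48507304372,0.502437013616
"f11",0.485038623037,0.500623544071,0.509812787295,0.504186992291
"f12",0.500922379474,0.509299450988,0.503170662485,0.486323064824
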