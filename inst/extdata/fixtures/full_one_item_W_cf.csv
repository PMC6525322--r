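"unit","c1","c2","c3","c4"
"f1",0.224832895118,0.163904905206,0.227281491017,0.933235487518
"f2",0.504524464059,0.487997924133,0.496807887054,0.51038712226
"f3",0.488894253783,0.501585490405,0.506917347443,0.502423334743
"f4",0.497574685763,0.50671505163,0.499299488035,0.496345957762
"f5",0.47093965883,0.479021034489,0.484175104767,0.560650652529
"f6",0.48711404464,0.483402708276,0.482782703421,0.544024439178
"f7",0.393324711161,0.323301569219,0.426045180201,0.747835056251
"f8",0.488198737109,0.492550627256,0.48293691048,0.53462866849
"f9",0.470182037926,0.471398865863,0.492934511891,0.560113852231
"f10",0.488852181068,0.493265170184,0.477031643564,0.538659287479
"f11",0.372919623394,0.303204960642,0.415930322067,0.772010151173
"f12",0.487667208866,0.499691275684,0.491740510697,0.520269730564
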