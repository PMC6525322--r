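"unit","c1","c2","c3","c4"
"f1",0.0203538782309,0.0203871129571,0.0169500629128,0.999441234207
"f2",0.508563183408,0.491430471371,0.502979138684,0.496861717522
"f3",0.490220219355,0.494118547578,0.501708779336,0.513633427857
"f4",0.0236294278147,0.0126067986581,0.0474627123686,0.998513900606
"f5",0.0150103346343,0.00454649724766,0.0361335971074,0.999223890015
"f6",0.494100705393,0.506729073185,0.499904065902,0.499185400641
"f7",0.49693576558,0.501465056229,0.492564745327,0.508888606602
"f8",0.271657565326,0.25865366143,0.345031838513,0.860379846953
"f9",0.495710844908,0.492130855295,0.499132583107,0.512781282798
"f10",0.507045526537,0.509264642673,0.500858387596,0.482384943086
"f11",0.0608195554192,0.0692053319933,0.0596538844687,0.993958257559
"f12",0.0166240034167,0.00575751956454,0.0383003275006,0.999111394386
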