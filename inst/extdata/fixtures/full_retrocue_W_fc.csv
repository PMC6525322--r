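"unit","f1","f2","f3","f4","f5","f6","f7","f8","f9","f10","f11","f12"
"c1",0.290981002756,0.257357286609,0.254969205683,0.338464352582,0.33431978476,0.258446311833,0.25972021793,0.290869372709,0.255982240559,0.264069781359,0.276459317879,0.356674304843
"c2",0.350091075571,0.25159807905,0.248463098415,0.298674185502,0.356304122784,0.251825438032,0.255087363984,0.28015043469,0.249291243226,0.257263114548,0.317130762028,0.316811619594
"c3",0.233253122924,0.208781250826,0.201677998731,0.448678515802,0.33382769943,0.204991076666,0.215052503384,0.343905288105,0.201699757253,0.202651055107,0.217960397135,0.461280030444
"c4",0.00807112932392,6.38602759858e-07,7.08285594317e-07,0.573354867854,0.562158971692,6.13174876461e-07,6.31307337345e-07,0.00282722952339,1.29317434015e-05,1.38244904751e-05,0.00480121707844,0.595940682999
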