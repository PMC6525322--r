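"unit","c1","c2","c3","c4"
"f1",0.50516104847,0.490372674507,0.502531879081,0.501805406221
"f2",0.494718646099,0.49728270625,0.509710904879,0.498154759803
"f3",0.501525145395,0.490162700353,0.511325737311,0.496748473658
"f4",0.503622073177,0.494358426933,0.508920712533,0.49292419446
"f5",0.495444139143,0.513024623403,0.492292908492,0.498987507879
"f6",0.510887751397,0.504207250818,0.492048919636,0.492601882234
"f7",0.488426212525,0.497110032102,0.511239053295,0.502947394155
"f8",0.502485318015,0.496841650235,0.498055719957,0.502590668028
"f9",0.498421744425,0.495333989865,0.515722031465,0.490153842615
"f10",0.493378780925,0.498481396991,0.497979373532,0.510010018454
"f11",0.500005987194,0.504775648485,0.485069996506,0.509806488736
"f12",0.500698080591,0.491307737145,0.508334668247,0.499513768151
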