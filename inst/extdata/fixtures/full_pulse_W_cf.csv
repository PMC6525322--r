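"unit","c1","c2","c3","c4"
"f1",0.493612750299,0.507566278778,0.495825892425,0.502871365054
"f2",0.507306845608,0.498089704562,0.495269324803,0.499254150226
"f3",0.41110982916,0.485518136511,0.538319481914,0.552696103549
"f4",0.0594486006047,0.0375828210211,0.035047071784,0.996907768156
"f5",0.399727338488,0.469325764798,0.512173170946,0.598021759074
"f6",0.511153262659,0.504561995996,0.480896769431,0.502869596834
"f7",0.494079912629,0.509952851451,0.506678473207,0.488988807666
"f8",0.0796226686356,0.0643808458284,0.0614097674701,0.992846502632
"f9",0.382415454598,0.472195854968,0.516724555874,0.60314610833
"f10",0.492128175791,0.505130919976,0.489264121531,0.513101580254
"f11",0.499647015609,0.513998147513,0.495680520777,0.490366786669
"f12",0.0811068672919,0.0636585275276,0.0605034456499,0.992828585918
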