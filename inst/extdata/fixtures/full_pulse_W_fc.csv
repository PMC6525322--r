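"unit","f1","f2","f3","f4","f5","f6","f7","f8","f9","f10","f11","f12"
"c1",0.235132483848,0.228140160875,0.295525595147,0.435312241328,0.294611997866,0.230484119433,0.24057290256,0.332385113611,0.285634822259,0.238113169465,0.240115257564,0.334092567007
"c2",0.221965812656,0.22866902087,0.375580475593,0.340395003947,0.368347411262,0.224214172448,0.228161863185,0.292446114443,0.356978759401,0.228795646122,0.240515787409,0.283458466149
"c3",0.210399200437,0.210813539216,0.404101602994,0.310595328177,0.417270695104,0.213083786874,0.214338065652,0.253971681749,0.401249292272,0.224225460594,0.223936414129,0.245223858282
"c4",0.00299516690369,0.00293412157451,0.0126793031877,0.596717624529,0.0164831917179,0.00381531975872,0.0034038370479,0.562982219668,0.0167342493815,0.00416137603112,0.0034748660222,0.571133510542
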