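"unit","f1","f2","f3","f4","f5","f6","f7","f8","f9","f10","f11","f12"
"c1",0.294114823,0.280271411038,0.276745193068,0.282128979166,0.287908308308,0.293467843145,0.288760898245,0.296965268457,0.293213142094,0.296605800589,0.288814292994,0.284273292484
"c2",0.289662551749,0.273875947695,0.287584784634,0.28654062695,0.300873189006,0.280682486935,0.291776821052,0.292287886686,0.297673242597,0.288061266331,0.294859151759,0.27905770713
"c3",0.287410441105,0.287280902394,0.28424608588,0.282574735056,0.293801202666,0.295359254279,0.283952071835,0.303894154843,0.290985710094,0.281774887035,0.282703812521,0.289296932153
"c4",0.294563296271,0.288576283204,0.287484900221,0.283960728332,0.281380823062,0.297809958226,0.290791899844,0.285742435897,0.291639662509,0.283612098422,0.292998401328,0.285066210517
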