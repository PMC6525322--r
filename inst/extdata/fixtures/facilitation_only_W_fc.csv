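"unit","f1","f2","f3","f4","f5","f6","f7","f8","f9","f10","f11","f12"
"c1",0.290119987916,0.290321325479,0.288114984258,0.285061767986,0.290400968092,0.283805834785,0.298394946642,0.288782244445,0.291146904607,0.282932836258,0.28553051794,0.289162714188
"c2",0.292364685214,0.279841675409,0.292112100312,0.285712099649,0.291247012396,0.281041752633,0.290796998319,0.286550685854,0.294212165593,0.296862050501,0.285858673013,0.286991479691
"c3",0.291521610985,0.285974774947,0.287166621408,0.285567034155,0.298423001247,0.28584080667,0.287289858075,0.290023292625,0.290717253367,0.289290288748,0.274802311117,0.29679698274
"c4",0.287688211979,0.289537563615,0.290972537624,0.278562858497,0.286065950121,0.291896234568,0.288110817358,0.295426050968,0.285743377742,0.28886787568,0.290686587538,0.290218976322
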