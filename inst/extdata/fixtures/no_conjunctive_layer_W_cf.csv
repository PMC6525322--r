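"unit","c1","c2","c3","c4"
"f1",0.487223783245,0.504276874171,0.500488016355,0.507769204169
"f2",0.487730262909,0.504511330383,0.519845972986,0.487183407485
"f3",0.504063026146,0.497256579428,0.493569678436,0.505020130705
"f4",0.503718799242,0.491967027881,0.493859606768,0.510233773453
"f5",0.499571958361,0.495723011276,0.501563238003,0.503111193272
"f6",0.496816755838,0.498851655309,0.503554178021,0.500752760263
"f7",0.505110746238,0.516973026214,0.483180642231,0.494103725117
"f8",0.491126770461,0.511911339829,0.502405468302,0.494297502433
"f9",0.51011085226,0.481483432754,0.497456258553,0.510389942315
"f10",0.500298010756,0.500087068396,0.500313577604,0.499300659445
"f11",0.49909719232,0.505080731254,0.492718770533,0.503014573048
"f12",0.510483851481,0.495202825395,0.491665230756,0.502439747595
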