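"unit","f1","f2","f3","f4","f5","f6","f7","f8","f9","f10","f11","f12"
"c1",0.500171231183,0.214689204267,0.225065063183,0.221765864107,0.232194092432,0.228697093374,0.378852207062,0.230613523753,0.229670517945,0.227574731432,0.37941824402,0.229080434811
"c2",0.383568151401,0.263436836841,0.269184992674,0.266825451657,0.267790490868,0.261887087257,0.319664513151,0.267456905496,0.27169256733,0.273698070374,0.322518935964,0.270294255641
"c3",0.483246090172,0.217875106629,0.213864415649,0.216937216035,0.217229329065,0.220776941928,0.405115698197,0.224333347724,0.219746976142,0.223407523815,0.413918696158,0.215175158169
"c4",0.83239829028,0.0658739380996,0.0643698813229,0.0669091573331,0.117917991921,0.106926377996,0.313705112474,0.0934745482021,0.111074806177,0.100717698756,0.363932973124,0.0820866946665
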