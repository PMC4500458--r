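species,floating_leaf,perennial,tuber,mean_julian_flowering_date,flowering_duration,ramet_size,shoot_height,stem_diameter,sla,ldmc,lamina_thickness,rooting_depth,sdmc,leaf_n,leaf_c,leaf_cn
Potamogeton_praelongus,1,2,1,142.53,31.751,181.47,111.6,1.5502,15.293,0.11608,0.24343,10.538,0.13576,15.387,369.55,14.616
Potamogeton_pectinatus,1,2,1,206.78,20.483,29.388,68.14,1.2203,18.369,0.10393,0.16428,5.966,0.11216,14.476,423.73,16.806
Potamogeton_perfoliatus,2,2,1,159,32.492,22.375,461.12,0.7303,14.012,0.094271,0.24793,22.337,0.17511,27.722,302.63,16.662
Najas_marina,1,2,1,213.14,38.58,43.73,34.554,0.95978,27.006,0.07636,0.27962,21.275,0.18304,27.82,359.82,21.552
Potamogeton_lucens,1,2,2,186.78,58.305,50.921,41.055,1.1888,17.198,0.092569,0.31834,14.946,0.1481,44.835,388.97,30.245
Hydrilla_verticillata,1,1,2,210.63,54.939,187.27,41.358,0.83569,25.063,0.11819,0.11719,26.461,0.14356,22.535,331.34,12.248
Myriophyllum_spicatum,1,2,1,136.2,34.337,50.288,74.57,3.0443,18.255,0.18876,0.18987,10.289,0.16462,33.477,384.58,23.453
Potamogeton_maackianus,1,1,1,223,54.996,20.731,89.203,1.4241,8.736,0.063249,0.14893,7.0329,0.14426,22.401,342.34,9.7408
Ceratophyllum_demersum,1,2,1,178.52,48.211,98.896,190.53,0.63724,40.048,0.090619,0.31321,8.6647,0.15516,23.453,331.2,16.435
Vallisneria_natans,1,1,1,203.75,58.442,156.79,46.607,2.2017,27.904,0.11089,0.20119,15.228,0.16646,18.032,352.72,19.827
Polygonum_amphibium,1,2,2,250.06,45.424,29.054,139.52,1.1439,16.643,0.12064,0.35996,3.2336,0.08359,23.558,354.23,20.425
Trapa_natans,1,2,1,210.78,94.728,100.04,92.056,2.0454,23.449,0.15375,0.21486,20.701,0.15843,45.302,322.45,15.822
Potamogeton_malaianus,2,2,2,208.35,19.954,9.3769,54.937,1.9762,21.918,0.089973,0.24791,7.9531,0.17882,15.232,389.03,10.514
Potamogeton_intortifolius,1,1,1,176.72,57.539,27.412,119.47,0.88181,21.758,0.1142,0.41834,7.4991,0.12794,28.602,375.92,18.149
Hydrocharis_dubia,1,1,1,175.21,49.692,18.39,121.67,1.7408,24.624,0.10526,0.18505,8.6494,0.14665,28.576,359.58,23.958
Potamogeton_distinctus,2,2,1,229.93,34.762,10.682,36.57,1.1248,13.206,0.12084,0.21736,7.2245,0.17416,29.727,423.49,9.6184
Nymphoides_peltatum,1,1,1,183.64,38.601,56.388,102.41,2.0745,18.786,0.079057,0.1096,12.656,0.11914,19.367,354.46,8.0594
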