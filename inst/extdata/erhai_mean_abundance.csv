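plot_id,site_id,depth_m,Potamogeton_praelongus,Potamogeton_pectinatus,Potamogeton_perfoliatus,Najas_marina,Potamogeton_lucens,Hydrilla_verticillata,Myriophyllum_spicatum,Potamogeton_maackianus,Ceratophyllum_demersum,Vallisneria_natans,Polygonum_amphibium,Trapa_natans,Potamogeton_malaianus,Potamogeton_intortifolius,Hydrocharis_dubia,Potamogeton_distinctus,Nymphoides_peltatum
d0.5,erhai,0.5,0.011,0.022,0.052,0.003,0.051,0.197,0.093,0.039,0.020,0.116,0.020,0.096,0.148,0.026,0.000,0.066,0.041
d1.0,erhai,1.0,0.000,0.002,0.058,0.000,0.220,0.071,0.094,0.039,0.017,0.075,0.083,0.084,0.145,0.053,0.016,0.024,0.019
d1.5,erhai,1.5,0.000,0.014,0.023,0.001,0.072,0.089,0.038,0.176,0.023,0.199,0.005,0.188,0.134,0.018,0.000,0.000,0.020
d2.0,erhai,2.0,0.000,0.019,0.036,0.000,0.171,0.070,0.025,0.279,0.050,0.182,0.000,0.061,0.092,0.008,0.000,0.000,0.007
d2.5,erhai,2.5,0.000,0.000,0.052,0.000,0.090,0.065,0.011,0.273,0.055,0.259,0.000,0.046,0.076,0.071,0.000,0.000,0.000
d3.0,erhai,3.0,0.000,0.001,0.000,0.000,0.074,0.038,0.024,0.301,0.010,0.403,0.000,0.020,0.101,0.027,0.000,0.000,0.000
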