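year,source,ef_so2_kgt,so2_t,desulf_rate,ef_pm10_kgt,pm10_t
2010,key_plot,NA,26036.38,0.6,2.97,5864.63
2010,urban_residential,NA,8026.77,0,0.15,42.81
2010,rural_residential,0.4,478.5,NA,3.74,4476.55
2010,agricultural,0.4,593.8,NA,10,14884
2020,key_plot,NA,17746.32,0.6,2.97,3997.31
2020,urban_residential,NA,9565.23,0,0.15,51.02
2020,rural_residential,0.4,430.65,NA,3.74,4028.9
2020,agricultural,0.4,62.8,NA,10,1574.25
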