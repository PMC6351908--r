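year,vehicle_type,ef_so2_gkm,so2_t,ef_pm10_gkm,pm10_t
2010,large_vehicle,0.05,786.52,0.02,314.61
2010,medium_vehicle,0.01,153.69,0.02,307.37
2010,small_car,0.01,2118.24,0.02,4236.48
2010,mini_vehicle,0.01,98.59,0.02,197.19
2010,heavy_truck,0.10,8918.00,0.02,1783.60
2010,medium_truck,0.05,1305.68,0.02,522.27
2010,light_truck,0.01,375.40,0.02,750.80
2010,mini_truck,0.01,2.18,0.02,4.36
2010,tricar,0.05,1721.37,0.02,688.55
2020,large_vehicle,0.030,490.79,0.012,196.32
2020,medium_vehicle,0.006,95.90,0.012,191.80
2020,small_car,0.006,3029.09,0.012,6058.17
2020,mini_vehicle,0.006,140.99,0.012,281.98
2020,heavy_truck,0.060,5564.83,0.012,1112.97
2020,medium_truck,0.030,814.74,0.012,325.90
2020,light_truck,0.006,234.25,0.012,468.50
2020,mini_truck,0.006,1.36,0.012,2.72
2020,tricar,0.030,1074.13,0.012,429.65
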