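area,child_population,n_facilities,children_per_facility,area_km2,mean_time_min,D,rank_D,D_bar,ratio,rank_ratio
Chubu,80926,30,2697.5,1190.98,1.830,1.081,3,0.456,2.370,2
Hohi,7386,4,1846.5,1081.03,5.994,0.930,1,0.340,2.736,3
Hokubu,23190,6,3865.0,1136.85,3.466,1.077,2,0.341,3.159,5
Nambu,10203,4,2550.8,903.40,4.639,1.147,5,0.257,4.464,6
Seibu,14416,4,3604.0,1224.04,7.023,1.083,4,0.367,2.950,4
Tobu,26855,14,1918.2,803.03,4.002,1.337,6,0.732,1.827,1
Total,162976,62,2628.6,6339.33,3.245,1.239,NA,NA,NA,NA
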