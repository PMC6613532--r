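band,annual_temperature,seasonality_temperature,annual_precipitation,seasonality_precipitation,annual_uv_radiation,range_heterogeneity,shannon_heterogeneity,altitude_mean,altitude_range,band_area,kernel_density_river
18,11.2317,399.065,10,5,7287.84,100,13567.8,3329.37,300,29441800,0.0539379
19,12.6565,378.865,10,5,6364.78,252.222,10338.3,2774,300,26216700,0.0807958
20,11.8631,341.831,10,8.06751,6586.94,100,19707.7,2737.04,575.257,25088300,0.0785372
21,12.8112,316.333,10,12.6038,5626.51,1081.89,8733.2,3096.66,583.043,23568600,0.0928233
22,9.50465,356.849,46.2321,9.82409,6071.91,662.212,18241.5,2402.85,1825.53,26227000,0.170233
23,12.4684,353.702,10,23.4265,6046.62,1058.02,22711.3,2687.84,2168.67,26875200,0.0997623
24,10.6645,339.928,123.656,26.2055,6834.82,2072.74,18198.4,2013.22,1574.08,20508100,0.0598159
25,11.1053,377.341,10,38.5211,6358.17,2396.22,18989.5,2313.94,1964.9,23857100,0.124284
26,11.2968,353.603,261.424,30.7515,5340.88,1271.52,25775.5,2462.41,1998.5,24678100,0.0706223
27,10.4782,318.19,188.149,15.6257,5361.35,2214,23318.7,1809.41,2247.87,25222300,0.24555
28,9.21776,311.837,248.501,25.8908,4778.1,3004.34,25981.3,1821.86,2238.88,17797300,0.0630005
29,10.6211,320.103,526.635,72.7533,4928.81,3036.86,28808.2,1802.46,3169.16,15632900,0.299673
30,10.2947,343.534,674.405,42.9099,5039.88,3086.11,25863.3,1355.27,3506.6,23579200,0.186166
31,10.1764,337.606,579.931,46.2808,5430.82,3719.08,25135.9,1219.92,2067.89,22239500,0.161303
32,10.3069,323.516,846.284,61.3236,4796.38,3226.28,20462,1483.74,3430.9,19678500,0.215993
33,9.56317,289.302,740.882,50.8317,3986.32,3164.25,23142.8,1496.7,2530.24,16810100,0.190409
34,8.12438,282.811,561.882,60.0925,4442.32,4487.26,27511,1267.16,2967.54,18111800,0.322272
35,9.54216,330.334,995.708,66.494,3594.82,3124.99,23794.1,1872.77,2447.09,21243600,0.24838
36,8.9547,307.583,716.635,77.9599,3602.78,3463,25614.8,1485.05,3349.43,15282800,0.155094
37,9.22326,339.093,931.847,85.2854,3504.17,2600.79,23561.5,1487.73,3418.6,19743800,0.27035
38,9.02272,289.077,711.33,75.9148,2936.72,3151.55,24973.4,797.53,2679.68,20673200,0.279655
39,8.61682,275.974,1300.32,68.4786,4369,4334.52,25797.3,894.026,3409.5,13509800,0.366438
40,7.00343,296.546,933.676,68.1826,2891.66,3969.53,25296.6,1138.31,3350.97,9646730,0.344684
41,6.91822,287.569,1436.59,60.1942,3753.06,3415.35,26349.3,1081.25,2762.86,23822100,0.397202
42,7.2331,265.278,1231.83,90.7063,3064.07,2599.52,23334.4,426.147,2258.58,11359200,0.504673
43,6.52544,273.988,1755.99,54.1701,2534.81,2037.13,22219.7,986.781,2561.8,13354700,0.352334
44,6.44267,259.817,1923.96,79.9697,2567.75,2440.78,21547.9,1074.08,2624.54,21553800,0.436372
45,6.5955,296.459,1616.03,92.1821,3139.63,1791.43,23379.6,806,3550.71,19435900,0.383561
46,7.20426,252.8,2012.19,107.302,2936.2,1208.19,27012.9,100,2307.47,11180600,0.491307
47,7.37867,211.543,1594.79,87.1601,1929.34,1026.83,20731,189.338,1807.4,14230600,0.338109
48,6.22426,265.409,1333.07,116.552,1897.23,2008.13,22946.3,604.681,1687.27,15295800,0.437267
49,6.13145,271.455,1847.68,123.466,1369.42,1564.25,15368.9,264.17,2194.93,14688400,0.489238
50,5.07537,239.153,1679.36,102.42,1785.32,100,21871.7,222.873,1769.75,17879000,0.542786
51,4.66243,251.033,2029.4,122.223,2008.67,1003.16,21256.9,100,1581.87,10441600,0.538204
52,5.21872,230.235,1957.85,112.903,1662.03,100,21797.7,100,1780.23,19946400,0.6
53,4.17655,230.807,2428.8,109.813,1131.87,100,14304.5,100,705.108,14599100,0.6
54,4.81183,266.326,2184.91,120.08,1354.88,100,17487.5,190.792,409.595,14494900,0.6
55,3.32161,225.175,2695.68,120.826,1184.26,100,15463.4,100,300,14026300,0.535195
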