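species,lat_min,lat_max
sp001,35.108,36.144
sp002,20.035,21.33
sp003,35.231,37.393
sp004,49.863,51.854
sp005,28.84,30.285
sp006,36.725,38.852
sp007,50.092,53.881
sp008,44.519,49.603
sp009,44.28,45.282
sp010,32.205,33.737
sp011,23.246,27.471
sp012,28.573,30.169
sp013,22.757,24.004
sp014,28.536,30.047
sp015,28.986,30.83
sp016,37.607,39.151
sp017,46.502,49.109
sp018,36.417,37.817
sp019,46.313,47.939
sp020,48.449,51.021
sp021,40.321,41.389
sp022,50.441,52.635
sp023,21.781,24.386
sp024,22.42,23.56
sp025,21.064,23.445
sp026,25.038,26.311
sp027,49.4,52.017
sp028,28.802,33.946
sp029,38.918,42.596
sp030,42.564,43.784
sp031,53.022,55.289
sp032,41.041,42.107
sp033,32.904,34.034
sp034,39.188,40.246
sp035,26.433,29.797
sp036,48.073,54.213
sp037,43.062,45.462
sp038,54.205,55.903
sp039,38.976,42.808
sp040,35.248,37.376
sp041,27.09,31.019
sp042,47.347,53.599
sp043,35.573,38.854
sp044,39.541,41.004
sp045,29.47,30.687
sp046,20.454,22.328
sp047,52.459,53.749
sp048,39.715,43.563
sp049,29.996,31.776
sp050,29.936,36.166
sp051,18.396,19.722
sp052,42.223,43.228
sp053,44.527,45.955
sp054,38.47,39.639
sp055,49.292,51.121
sp056,37.05,38.942
sp057,30.928,34.783
sp058,45.986,47.782
sp059,40.085,45.939
sp060,45.872,47.085
sp061,30.951,33.288
sp062,38.128,43.931
sp063,34.011,36.639
sp064,38.675,42.55
sp065,53.434,54.848
sp066,20.652,22.728
sp067,36.42,37.707
sp068,41.328,47.588
sp069,30.76,32.897
sp070,25.928,27.071
sp071,21.902,23.169
sp072,41.639,43.235
sp073,38.282,40.497
sp074,39.388,43.459
sp075,27.409,28.516
sp076,40.089,47.736
sp077,41.606,46.467
sp078,41.802,50.082
sp079,22.831,25.403
sp080,36.293,38.75
sp081,40.69,41.833
sp082,25.676,27.116
sp083,20.061,21.074
sp084,42.991,52.527
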