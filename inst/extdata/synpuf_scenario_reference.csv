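scenario,n_records,limited_pct_1,limited_classes_1,limited_pct_2,limited_classes_2,limited_pct_5,limited_classes_5,safe_pct_1,safe_classes_1,safe_pct_2,safe_classes_2,safe_pct_5,safe_classes_5,gap_pct_1,gap_pct_2,gap_pct_5
diagnosis,3369468,71.465,2407996,11.049,186162,2.333,15726,41.595,1401556,14.248,240043,4.412,29737,29.869,35.361,19.986
procedure,3105665,76.123,2364135,9.902,153767,1.731,10752,31.251,970568,12.472,193672,4.460,27708,44.871,42.301,33.173
drug_treatment,1300649,95.475,1241796,0.895,5826,0.306,796,5.558,72292,1.625,10569,0.356,927,89.917,89.187,88.611
lab_test,1622884,93.012,1509486,5.043,40923,0.138,448,16.749,271819,7.748,62875,2.385,7744,76.263,73.558,64.958
medical_history,1348569,92.353,1245455,4.286,28900,0.224,606,12.079,162898,4.466,30115,1.550,4183,80.274,80.094,76.759
death,1218881,99.997,1218845,0.003,18,0,0,0.784,9557,0.686,4185,0.719,1755,99.212,98.529,0
device_treatment,1247726,97.647,1218368,0.152,954,0.059,149,1.464,18271,0.380,2372,0.139,348,96.182,95.955,95.625
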