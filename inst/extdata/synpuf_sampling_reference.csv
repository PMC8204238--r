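sample_size,scenario,limited_mean,limited_pct,safe_mean,safe_pct,gap_pct
1000,diagnosis,999.800,99.980,998.580,99.858,0.122
1000,procedure,999.760,99.976,997.400,99.740,0.236
1000,drug_treatment,999.860,99.986,889.470,88.947,11.039
1000,lab_test,999.900,99.990,956.910,95.691,4.299
1000,medical_history,999.960,99.996,932.320,93.232,6.764
1000,death,999.990,99.999,899.830,89.983,10.016
1000,device_treatment,999.800,99.980,870.000,87.000,12.980
10000,diagnosis,9975.850,99.759,9868.540,98.685,1.073
10000,procedure,9974.680,99.747,9743.830,97.438,2.309
10000,drug_treatment,9980.620,99.806,4642.820,46.428,53.378
10000,lab_test,9993.920,99.939,7320.070,73.201,26.739
10000,medical_history,9989.730,99.897,6226.700,62.267,37.630
10000,death,9999.980,99.999,4851.230,48.512,51.487
10000,device_treatment,9983.140,99.831,3971.310,39.713,60.118
100000,diagnosis,97724.930,97.725,89757.540,89.758,7.967
100000,procedure,97742.680,97.743,82093.250,82.093,15.649
100000,drug_treatment,98419.410,98.419,12062.980,12.063,86.356
100000,lab_test,99375.690,99.376,42164.130,42.164,57.212
100000,medical_history,99022.020,99.022,28552.750,28.553,70.469
100000,death,99999.640,99.999,9106.630,9.107,90.892
100000,device_treatment,98804.960,98.805,5206.990,5.207,93.598
1000000,diagnosis,846819.090,84.682,603607.950,60.361,24.321
1000000,procedure,864575.710,86.458,472502.940,47.250,39.207
1000000,drug_treatment,957078.730,95.708,59825.330,5.983,89.725
1000000,lab_test,951528.090,95.153,206809.130,20.681,74.472
1000000,medical_history,936158.630,93.616,134617.450,13.462,80.154
1000000,death,999975.900,99.998,9344.160,0.934,99.063
1000000,device_treatment,976802.140,97.680,15496.020,1.550,96.131
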