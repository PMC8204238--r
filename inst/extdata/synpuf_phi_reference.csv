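variable,n_records,limited_unique,limited_pct,limited_max_ec,safe_unique,safe_pct,safe_max_ec,gap_pct,gap_max_ec
visit_start_date,1218881,771684,63.310,10,581,0.047,888,62.952,878
visit_end_date,1218881,771891,63.327,10,581,0.0395,889,62.960,879
death_date,1155,1141,98.787,2,1009,87.359,3,11.428,1
condition_start_date,3231730,146828,4.543,45,137,0.004,2391,4.538,2346
condition_end_date,3231730,146727,4.540,45,125,0.003,2393,4.536,2348
procedure_date,3024452,257161,8.502,64,201,0.006,2180,8.495,2116
measurement_date,741161,168180,22.691,43,595,0.080,575,22.610,532
observation_date,420986,182497,43.349,28,983,0.233,335,43.115,307
device_exposure_start_date,47655,13232,27.766,40,3190,6.693,218,21.073,178
device_exposure_end_date,47655,13219,27.739,40,3191,6.696,187,21.043,147
drug_exposure_start_date,158316,55042,34.767,45,2845,1.797,409,32.970,364
drug_exposure_end_date,158316,55042,34.767,45,2845,1.797,409,32.970,364
month_of_birth,25200,14508,57.571,8,3296,13.079,49,44.492,41
day_of_birth,25200,3296,13.079,49,3296,13.079,49,0,0
npi,1215317,865840,71.244,70,91,0.007,2247,71.236,2177
county,25200,18103,71.837,12,3296,13.079,49,58.757,37
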