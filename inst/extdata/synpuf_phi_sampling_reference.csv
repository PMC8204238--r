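sample_size,variable,limited_mean,limited_sd,limited_pct,safe_mean,safe_sd,safe_pct,gap_pct
1000,visit_start_date,999.26,1.125,99.926,859.68,16.229,85.968,13.958
1000,visit_end_date,999.78,0.629,99.978,861.71,15.086,86.171,13.807
1000,death_date,989.06,2.155,98.906,890.44,7.478,89.044,9.862
1000,condition_start_date,998.44,1.766,99.844,857.59,15.178,85.759,14.085
1000,condition_end_date,998.12,2.006,99.812,858.7,16.45,85.87,13.942
1000,procedure_date,998.24,1.804,99.824,858.61,16.504,85.861,13.963
1000,measurement_date,995.14,2.971,99.514,855.11,15.321,85.511,14.003
1000,observation_date,997.54,2.162,99.754,854.79,14.238,85.479,14.275
1000,device_exposure_start_date,877.05,13.107,87.705,539.75,16.877,53.975,33.73
1000,device_exposure_end_date,875.34,16.05,87.534,539.68,20.112,53.968,33.566
1000,drug_exposure_start_date,956.34,8.669,95.634,720.7,17.729,72.07,23.564
1000,drug_exposure_end_date,956.34,8.669,95.634,720.7,17.729,72.07,23.564
1000,month_of_birth,971.47,7.612,97.147,738.4,17.707,73.84,23.307
1000,day_of_birth,737.54,17.774,73.754,737.54,17.774,73.754,0
1000,npi,998.8,1.775,99.88,673.77,19.212,67.377,32.503
1000,county,979.69,6.59,97.969,738.46,16.856,73.846,24.123
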