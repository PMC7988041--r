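variable,mean,sd,se,cv_percent,ci_lower,ci_upper
max_pressure_SAS_BC_A,3592.3,344.0,103.7,9.6,3361.2,3823.4
max_pressure_SAS_BC_B,3009.9,284.7,85.8,9.5,2818.7,3201.2
max_pressure_SAS_BC_C,2516.5,117.1,35.3,4.7,2437.8,2595.1
experimental_ICP_SAS,2638.5,118.8,37.6,4.5,2638.5,2638.5
max_pressure_CA_BC_A,3568.9,348.7,105.1,9.8,3334.6,3803.1
max_pressure_CA_BC_B,2984.8,287.3,86.6,9.6,2791.8,3177.9
max_pressure_CA_BC_C,2503.5,115.9,35.0,4.6,2425.6,2581.4
ventricular_volume,281.6,11.5,3.5,4.1,273.9,289.3
brain_volume,1071.7,48.6,14.7,4.5,1039.0,1104.3
sas_volume,108.4,4.7,1.4,4.4,105.2,111.6
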