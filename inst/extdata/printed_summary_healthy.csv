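variable,mean,sd,se,cv_percent,ci_lower,ci_upper
max_pressure_SAS_BC_A,650.0,62.5,22.1,9.6,597.7,702.3
max_pressure_SAS_BC_B,586.2,58.0,20.5,9.9,537.7,634.7
max_pressure_SAS_BC_C,493.2,23.0,8.1,4.7,474.0,512.4
max_pressure_CA_BC_A,623.0,61.8,21.9,9.9,571.3,674.7
max_pressure_CA_BC_B,561.5,54.2,19.2,9.7,516.2,606.9
max_pressure_CA_BC_C,484.1,22.6,8.0,4.7,465.3,503.0
ventricular_volume,20.3,0.8,0.3,3.9,19.7,21.0
brain_volume,1297.0,52.1,18.4,4.0,1253.4,1340.5
sas_volume,105.9,4.8,1.7,4.5,101.8,109.9
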