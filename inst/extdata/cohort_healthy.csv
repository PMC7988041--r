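variable,unit,s1,s2,s3,s4,s5,s6,s7,s8
max_pressure_SAS_BC_A,Pa,599.6,699.1,719.1,704.2,589.3,594.3,710,584.3
max_pressure_SAS_BC_B,Pa,575.2,622.8,655.1,614.1,515.6,570.2,641.5,495.1
max_pressure_SAS_BC_C,Pa,505.4,508.5,515.9,499.1,462.1,489.2,510.7,454.9
max_pressure_CA_BC_A,Pa,565.3,640.3,701.2,665.1,570.3,580.6,703.1,557.8
max_pressure_CA_BC_B,Pa,569.5,597.4,636.8,583.3,492.1,529.3,598.8,485.1
max_pressure_CA_BC_C,Pa,481.2,502.4,508.3,494.1,453.1,481.3,503.2,449.4
ventricular_volume,ml,20.1,20.9,21.8,19.89,20.1,19.6,20.9,19.5
brain_volume,ml,1275.1,1343.2,1369.1,1338.1,1305.5,1259.2,1210.3,1275.1
sas_volume,ml,100.5,109.4,111.1,105.8,101.9,113.1,103.5,101.5
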