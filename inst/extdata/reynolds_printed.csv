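group,scheme,mean,se
patient,A,388.6,6.2
patient,B,374.3,5.9
patient,C,372.4,5.8
healthy,A,332.3,5.1
healthy,B,323.3,5.0
healthy,C,321.8,5.0
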