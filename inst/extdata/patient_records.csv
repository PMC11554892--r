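patient_id,fibrotic,nyha_class,esv,edv,sv,ef,p_d,p_s,hr
P2,FALSE,3,425,501,76,15.2,60,110,85
P3,FALSE,2,238,350,112,32.0,75,140,75
P4,FALSE,3,226,300,73,24.5,80,120,62
P6,TRUE,3,236,318,82,25.8,70,110,76
P8,TRUE,3,143,214,71,33.2,70,130,68
P11,TRUE,3,173,231,58,25.1,80,110,110
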