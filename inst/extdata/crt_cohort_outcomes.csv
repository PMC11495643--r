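patient_id,age,nyha_baseline,ef,qrsd,mrv,hr,nyha_followup,desv_lv
BiV1,84,3,38,156,NA,70,2,12
BiV2,65,4,26,148,16,70,1,-2
BiV3,79,3,35,162,NA,70,2,16
BiV4,64,2,25,130,36,70,1,-12
BiV5,61,3,17,182,14,60,2,15
BiV6,55,2,32,119,NA,70,1,59
BiV7,68,4,21,140,NA,70,4,-36
BiV8,54,3,29,120,NA,75,2,7
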