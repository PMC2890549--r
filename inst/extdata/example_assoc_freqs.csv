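snp_id,freq2_ase,freq2_rest
rs4742761,0.14,0.25
rs2416666,0.19,0.19
rs7874183,0.13,0.28
rs7034462,0.31,0.05
rs10819634,0.06,0.26
rs1888223,0.50,0.30
sig9A6A,0.31,0.04
rs10988705,0.00,0.04
rs6478974,0.50,0.47
rs10739778,0.38,0.36
rs2026811,0.25,0.32
rs10512263,0.00,0.11
rs11568785,0.25,0.02
rs334348,0.31,0.39
rs7871490,0.50,0.46
rs334349,0.25,0.43
rs7850895,0.07,0.06
rs1590,0.25,0.39
rs1626340,0.25,0.32
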