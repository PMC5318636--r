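landrace	category	count
indica_12	intergenic	1374419
indica_12	intron_and_regulatory	288375
indica_12	utrs	85749
indica_12	nonsynonymous	151998
indica_12	synonymous	107286
indica_13	intergenic	1329647
indica_13	intron_and_regulatory	279350
indica_13	utrs	82611
indica_13	nonsynonymous	131754
indica_13	synonymous	90790
indica_15	intergenic	1527754
indica_15	intron_and_regulatory	320956
indica_15	utrs	96948
indica_15	nonsynonymous	172767
indica_15	synonymous	122993
japonica_11	intergenic	488888
japonica_11	intron_and_regulatory	109191
japonica_11	utrs	29587
japonica_11	nonsynonymous	66645
japonica_11	synonymous	45343
japonica_14	intergenic	454811
japonica_14	intron_and_regulatory	101187
japonica_14	utrs	28138
japonica_14	nonsynonymous	63962
japonica_14	synonymous	42817
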