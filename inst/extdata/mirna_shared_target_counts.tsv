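mirna_id	n_shared	n_B	n_A
hsa-miR-16-5p	483	1588	1014
hsa-miR-548c-3p	414	1424	882
hsa-miR-124-3p	449	1590	949
hsa-miR-1-3p	470	1604	1027
hsa-miR-34a-5p	415	1364	821
hsa-miR-155-5p	422	1331	841
hsa-miR-27a-3p	408	1376	868
hsa-miR-107	369	1240	760
hsa-let-7b-5p	379	1295	770
hsa-miR-590-3p	375	1259	800
hsa-miR-23b-3p	365	1143	737
hsa-miR-3163	353	1231	758
hsa-miR-374a-5p	338	1126	669
hsa-miR-186-5p	358	1211	745
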