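variable,level,Luminal A,Luminal N,Luminal B,Basal p53 altered,Basal p53 normal,HER2+/ER+,HER2+/ER-
size,<15 mm,89,67,50,12,18,7,11
size,>=15 mm,130,77,87,78,46,23,41
grade,1,75,47,35,1,3,3,1
grade,2,108,73,72,10,23,8,23
grade,3,40,32,33,82,42,20,31
lymph_node_stage,1,172,108,100,68,50,15,31
lymph_node_stage,2,44,40,36,18,18,10,15
lymph_node_stage,3,9,4,4,7,2,7,9
npi,Excellent,55,33,23,0,1,2,0
npi,Good,82,54,53,5,15,5,11
npi,Moderate 1,52,34,37,39,29,7,17
npi,Moderate 2,22,26,21,37,19,10,16
npi,Poor,11,4,4,8,4,6,8
npi,Very poor,0,0,2,4,0,2,3
adjuvant_therapy,Chemotherapy,5,12,4,25,21,6,16
adjuvant_therapy,Hormone therapy,185,100,112,42,32,19,26
adjuvant_therapy,Hormone therapy/chemotherapy,14,21,11,10,6,4,6
adjuvant_therapy,No therapy,21,19,13,16,11,3,7
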