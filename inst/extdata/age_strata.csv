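sex,age_lo,age_hi,practice,school,retrospective,retro_source
F,0,2,3953,0,1475,birth
F,2,4,1393,4,0,school_medical
F,4,6,1274,2,1768,school_medical
F,6,8,1046,198,405,school_medical
F,8,10,704,302,78,school_medical
F,10,12,1096,93,1254,school_medical
F,12,14,693,261,411,school_medical
F,14,16,605,447,391,school_medical
F,16,18,213,840,24,school_medical
F,18,20,25,466,100,military
F,20,22,1,0,0,military
M,0,2,3920,0,1511,birth
M,2,4,1457,4,2,school_medical
M,4,6,1475,3,1927,school_medical
M,6,8,1082,207,487,school_medical
M,8,10,660,321,84,school_medical
M,10,12,1126,106,1267,school_medical
M,12,14,716,210,387,school_medical
M,14,16,647,442,430,school_medical
M,16,18,219,838,16,school_medical
M,18,20,32,627,2495,military
M,20,22,4,66,1000,military
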