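origin,overall,german,romande,ticino
swiss_both,12791,9305,2763,723
north_central_eu_both,1698,1154,532,12
ita_spa_por_both,2665,1147,968,550
balkan_both,2915,2048,645,222
turkey_both,499,422,55,22
other_both,3095,1855,1055,185
mixed_non_swiss,1726,848,666,212
swiss_one,5375,3389,1483,503
unknown,12526,9659,2722,145
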