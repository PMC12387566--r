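origin,sex,n,overweight,obese
swiss_both,F,4009,9.8,1.9
north_central_eu_both,F,576,7.5,1.2
ita_spa_por_both,F,835,20.1,6.1
balkan_both,F,826,20.2,6.4
turkey_both,F,165,21.8,4.2
swiss_one,F,1696,11.1,1.7
other_mixed,F,1555,17.4,3.0
swiss_both,M,4108,10.2,1.6
north_central_eu_both,M,567,7.2,1.2
ita_spa_por_both,M,933,19.1,4.4
balkan_both,M,1055,27.2,8.5
turkey_both,M,176,25.6,6.2
swiss_one,M,1770,10.6,2.1
other_mixed,M,1629,16.9,3.7
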