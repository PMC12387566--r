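region,all_percentiles,band_97_100
german,2346,50
romande,971,38
ticino,373,14
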