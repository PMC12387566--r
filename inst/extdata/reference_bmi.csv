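sex,age,p3,p10,p25,p50,p75,p90,p97
F,2,13.8,14.4,15.1,16.0,16.9,17.8,18.9
F,3,13.5,14.1,14.8,15.6,16.6,17.6,18.7
F,4,13.2,13.8,14.5,15.4,16.4,17.4,18.7
F,5,13.1,13.7,14.4,15.3,16.4,17.5,19.0
F,6,12.9,13.6,14.3,15.3,16.5,17.9,19.7
F,7,12.9,13.6,14.4,15.5,16.9,18.5,20.6
F,8,12.9,13.7,14.6,15.8,17.3,19.2,21.7
F,9,13.1,13.9,14.9,16.2,18.0,20.0,22.8
F,10,13.4,14.3,15.4,16.9,18.8,21.0,24.0
F,11,13.8,14.8,15.9,17.5,19.6,22.0,25.2
F,12,14.3,15.3,16.6,18.3,20.4,23.0,26.4
F,13,14.9,16.0,17.3,19.0,21.3,24.0,27.5
F,14,15.6,16.7,18.0,19.8,22.1,24.8,28.5
F,15,16.2,17.3,18.6,20.4,22.7,25.4,29.2
F,16,16.7,17.8,19.0,20.8,23.1,25.8,29.6
F,17,17.1,18.1,19.4,21.1,23.4,26.1,29.8
F,18,17.4,18.4,19.7,21.4,23.7,26.3,29.9
M,2,14.0,14.6,15.3,16.1,17.1,18.2,19.4
M,3,13.7,14.2,14.9,15.7,16.7,17.7,18.9
M,4,13.4,14.0,14.7,15.5,16.5,17.5,18.8
M,5,13.3,13.9,14.6,15.5,16.5,17.6,19.0
M,6,13.1,13.8,14.5,15.5,16.7,17.9,19.4
M,7,13.0,13.7,14.5,15.6,16.9,18.3,20.1
M,8,13.0,13.8,14.7,15.8,17.3,18.9,21.0
M,9,13.2,14.0,15.0,16.3,17.9,19.8,22.2
M,10,13.5,14.4,15.4,16.8,18.6,20.7,23.6
M,11,13.9,14.8,15.9,17.4,19.4,21.7,24.9
M,12,14.3,15.2,16.4,18.0,20.1,22.6,26.1
M,13,14.7,15.7,16.9,18.6,20.8,23.5,27.2
M,14,15.2,16.3,17.5,19.3,21.6,24.3,28.2
M,15,15.8,16.9,18.2,20.0,22.3,25.2,29.1
M,16,16.5,17.6,18.9,20.7,23.1,26.0,29.9
M,17,17.0,18.2,19.5,21.4,23.8,26.7,30.7
M,18,17.5,18.7,20.1,22.0,24.4,27.3,31.3
M,19,17.9,19.1,20.5,22.4,24.9,27.9,32.0
M,20,18.2,19.4,20.9,22.8,25.4,28.4,32.6
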