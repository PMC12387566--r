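sex,age,p3,p10,p25,p50,p75,p90,p97
F,0,46.3,47.4,48.5,49.7,51.0,52.1,53.2
F,0.25,55.6,57.0,58.3,59.8,61.3,62.6,64.0
F,0.5,61.6,63.1,64.6,66.2,67.9,69.4,70.9
F,0.75,65.7,67.2,68.8,70.5,72.3,73.9,75.5
F,1,69.3,71.0,72.6,74.5,76.3,78.0,79.7
F,1.25,72.9,74.5,76.2,78.0,79.9,81.6,83.3
F,1.5,75.9,77.6,79.3,81.2,83.2,85.0,86.7
F,1.75,78.6,80.3,82.1,84.1,86.2,88.0,89.9
F,2,81.0,82.8,84.7,86.8,88.9,90.8,92.8
F,3,89.0,91.1,93.2,95.7,98.1,100.4,102.6
F,4,95.7,98.1,100.6,103.3,106.1,108.6,111.2
F,5,102.0,104.6,107.3,110.3,113.4,116.2,119.0
F,6,107.9,110.8,113.7,117.1,120.5,123.5,126.6
F,7,113.5,116.6,119.8,123.4,127.1,130.4,133.7
F,8,118.6,121.9,125.3,129.1,132.9,136.4,139.9
F,9,123.7,127.2,130.7,134.8,138.8,142.6,146.3
F,10,128.8,132.6,136.6,141.0,145.5,149.5,153.6
F,11,134.1,138.3,142.5,147.3,152.2,156.7,161.1
F,12,140.0,144.2,148.5,153.4,158.3,162.8,167.3
F,13,146.3,150.2,154.3,158.9,163.5,167.7,171.9
F,14,150.4,154.1,157.9,162.2,166.6,170.5,174.5
F,15,152.4,156.0,159.7,163.8,168.0,171.9,175.7
F,16,153.3,156.9,160.5,164.6,168.8,172.5,176.3
F,17,154.1,157.7,161.3,165.3,169.4,173.1,176.8
F,18,154.7,158.2,161.8,165.9,170.0,173.7,177.4
M,0,47.0,48.1,49.3,50.5,51.8,53.0,54.2
M,0.25,57.1,58.4,59.8,61.2,62.7,64.1,65.5
M,0.5,63.6,65.0,66.3,67.9,69.5,70.9,72.3
M,0.75,67.7,69.1,70.6,72.3,74.0,75.5,77.0
M,1,71.1,72.7,74.3,76.0,77.8,79.5,81.1
M,1.25,74.3,75.9,77.6,79.5,81.4,83.1,84.9
M,1.5,77.2,78.9,80.6,82.6,84.7,86.5,88.3
M,1.75,79.8,81.6,83.4,85.5,87.6,89.5,91.5
M,2,82.2,84.0,86.0,88.1,90.3,92.3,94.3
M,3,90.1,92.3,94.4,96.9,99.4,101.7,103.9
M,4,97.0,99.3,101.7,104.4,107.2,109.7,112.2
M,5,103.1,105.7,108.4,111.4,114.5,117.2,120.0
M,6,108.8,111.7,114.7,118.0,121.4,124.5,127.5
M,7,114.5,117.5,120.7,124.3,127.9,131.2,134.5
M,8,120.0,123.2,126.5,130.2,133.9,137.4,140.8
M,9,125.2,128.5,131.9,135.7,139.6,143.2,146.7
M,10,130.0,133.4,137.0,141.0,145.1,148.9,152.6
M,11,134.5,138.2,142.1,146.5,150.9,154.9,159.0
M,12,139.3,143.4,147.7,152.5,157.4,161.9,166.3
M,13,145.1,149.6,154.2,159.4,164.6,169.5,174.3
M,14,151.6,156.2,160.9,166.2,171.6,176.5,181.5
M,15,157.6,162.1,166.7,171.8,177.1,181.9,186.7
M,16,162.2,166.4,170.8,175.6,180.6,185.1,189.6
M,17,165.0,168.9,173.0,177.6,182.2,186.4,190.7
M,18,166.1,169.9,173.8,178.3,182.7,186.8,190.9
M,19,166.3,170.1,174.0,178.4,182.8,186.9,190.9
M,20,166.0,169.9,173.9,178.4,182.9,187.1,191.3
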