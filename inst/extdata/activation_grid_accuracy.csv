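neurons,tanh,tanh_sd,sigmoid,sigmoid_sd,relu,relu_sd
10,47.9,23.7,74.2,10.6,93.7,14.8
20,42.1,25.3,75.6,14.7,99.9,1.9
30,51.1,28.1,79.5,11.5,98.0,3.0
40,45.6,39.5,79.4,8.5,97.4,5.2
50,53.2,36.1,84.6,9.2,97.4,3.2
60,52.1,35.9,85.8,5.5,98.6,2.8
70,49.1,33.2,81.1,10.7,99.3,2.0
80,54.1,28.6,83.7,9.8,99.4,1.9
90,50.9,34.2,82.6,6.4,98.7,2.7
100,53.9,30.2,86.0,7.6,99.7,2.6
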