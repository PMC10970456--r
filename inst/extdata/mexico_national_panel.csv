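institution,state,gynecologists,exam_rooms,delivery_rooms,operating_rooms,prenatal_visits,deliveries,cesareans,abortions
A,National,4778,1041,2794,1887,46993718,2945997,1596098,586055
B,National,3832,429,393,1318,33035961,1065349,884649,270069
C,National,1109,223,150,330,5386732,50389,114625,31145
D,National,110,45,24,74,1080422,4714,11646,2043
E,National,71,84,44,98,777644,25895,14295,1112
F,National,43,38,27,45,284385,4468,6077,306
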