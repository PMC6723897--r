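setting_id,dr_nominal,hpmc_nominal,force,role
1,6,10,63.8,test
2,8,10,63.8,train
3,10,10,63.8,train
4,6,20,63.8,test
5,8,20,63.8,train
6,10,20,63.8,train
7,6,30,63.8,train
8,8,30,63.8,train
9,10,30,63.8,train
10,6,10,95.7,train
11,8,10,95.7,train
12,10,10,95.7,train
13,6,20,95.7,train
14,8,20,95.7,test
15,10,20,95.7,train
16,6,30,95.7,train
17,8,30,95.7,test
18,10,30,95.7,train
19,6,10,127.6,train
20,8,10,127.6,train
21,10,10,127.6,train
22,6,20,127.6,train
23,8,20,127.6,train
24,10,20,127.6,train
25,6,30,127.6,train
26,8,30,127.6,train
27,10,30,127.6,test
28,7,20,63.8,train
29,7.5,20,63.8,test
30,8.5,20,63.8,train
31,9,20,63.8,train
32,8,5,63.8,train
33,8,15,63.8,train
34,8,25,63.8,test
35,8,35,63.8,train
36,8,20,31.9,train
37,8,20,159.5,train
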