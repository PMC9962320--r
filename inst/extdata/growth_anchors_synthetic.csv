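age,height_cm,weight_kg
1,75,10.0
2,87,12.5
3,96,14.5
4,103,16.5
5,110,18.5
6,116,20.5
7,122,23.0
8,128,25.5
9,133,28.5
10,138,32.0
11,143,36.0
12,149,40.0
13,155,45.0
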