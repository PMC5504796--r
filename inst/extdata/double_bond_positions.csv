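fa,positions
14:1,9
15:1,10
16:1,9
16:2,9;12
17:1,9
17:2,9;12
18:1,9
18:2,9;12
18:3,9;12;15
18:4,6;9;12;15
19:1,10
19:2,10;13
20:1,11
20:2,11;14
20:3,8;11;14
20:4,5;8;11;14
20:5,5;8;11;14;17
22:1,13
22:2,13;16
22:3,10;13;16
22:4,7;10;13;16
22:5,7;10;13;16;19
22:6,4;7;10;13;16;19
24:1,15
24:2,15;18
24:6,6;9;12;15;18;21
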