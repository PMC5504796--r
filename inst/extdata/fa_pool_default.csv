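fa
12:0
13:0
14:0
15:0
16:0
17:0
18:0
19:0
20:0
21:0
22:0
23:0
24:0
14:1
15:1
16:1
17:1
18:1
19:1
20:1
22:1
24:1
16:2
17:2
18:2
18:3
18:4
19:2
20:2
20:3
20:4
20:5
22:2
22:3
22:4
22:5
22:6
24:2
24:6
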