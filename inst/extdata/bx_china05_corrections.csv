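gp_ba,correction_boys,correction_girls,terminal
2.0,0.0,-0.2,FALSE
2.5,-0.1,-0.2,FALSE
3.0,-0.2,0.1,FALSE
3.5,-0.2,0.3,FALSE
4.0,-0.1,0.4,FALSE
4.5,0.0,0.4,FALSE
5.0,0.0,0.3,FALSE
5.5,0.1,0.1,FALSE
6.0,0.2,-0.1,FALSE
6.5,0.3,-0.1,FALSE
7.0,0.5,0.2,FALSE
7.5,0.6,0.3,FALSE
8.0,0.5,0.2,FALSE
8.5,0.4,0.1,FALSE
9.0,0.3,0.0,FALSE
9.5,0.2,-0.1,FALSE
10.0,0.1,-0.1,FALSE
10.5,0.0,-0.2,FALSE
11.0,-0.1,-0.2,FALSE
11.5,-0.2,-0.3,FALSE
12.0,-0.4,-0.5,FALSE
12.5,-0.5,-0.6,FALSE
13.0,-0.4,-0.7,FALSE
13.5,-0.4,-0.8,FALSE
14.0,-0.4,-0.9,FALSE
14.5,-0.5,-1.0,FALSE
15.0,-0.7,-1.2,FALSE
15.5,-0.9,-1.2,FALSE
16.0,-1.0,-1.1,FALSE
16.5,-1.1,-1.1,FALSE
17.0,-1.2,-1.2,TRUE
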