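"trial","side","cue_time","time_s"
1,"right",2,4
2,"left",10,12
3,"right",18,20
4,"right",26,28
5,"left",34,36
6,"left",42,44
7,"left",50,52
8,"right",58,60
9,"right",66,68
10,"right",74,76
11,"left",82,84
12,"right",90,92
13,"left",98,100
14,"right",106,108
15,"left",114,116
16,"left",122,124
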