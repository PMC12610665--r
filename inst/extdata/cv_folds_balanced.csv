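fold,actual,AS,MR,MS,MVP,N
1,AS,20,0,0,0,0
1,MR,0,19,1,0,0
1,MS,0,0,20,0,0
1,MVP,1,0,0,19,0
1,N,0,0,0,0,20
2,AS,20,0,0,0,0
2,MR,0,20,0,0,0
2,MS,0,0,20,0,0
2,MVP,0,0,0,20,0
2,N,0,0,0,0,20
3,AS,20,0,0,0,0
3,MR,0,20,0,0,0
3,MS,0,0,20,0,0
3,MVP,0,0,0,20,0
3,N,0,0,0,0,20
4,AS,20,0,0,0,0
4,MR,0,20,0,0,0
4,MS,0,0,20,0,0
4,MVP,0,0,0,20,0
4,N,0,0,0,0,20
5,AS,20,0,0,0,0
5,MR,0,20,0,0,0
5,MS,0,0,20,0,0
5,MVP,0,0,0,20,0
5,N,0,0,0,0,20
6,AS,19,1,0,0,0
6,MR,0,20,0,0,0
6,MS,0,0,20,0,0
6,MVP,0,0,0,20,0
6,N,0,0,0,0,20
7,AS,20,0,0,0,0
7,MR,0,19,1,0,0
7,MS,0,0,20,0,0
7,MVP,0,0,0,20,0
7,N,0,0,0,0,20
8,AS,20,0,0,0,0
8,MR,0,20,0,0,0
8,MS,0,0,20,0,0
8,MVP,0,0,0,20,0
8,N,0,0,0,0,20
9,AS,20,0,0,0,0
9,MR,0,20,0,0,0
9,MS,0,0,20,0,0
9,MVP,0,0,0,20,0
9,N,0,0,0,0,20
10,AS,20,0,0,0,0
10,MR,0,20,0,0,0
10,MS,0,0,20,0,0
10,MVP,0,0,0,20,0
10,N,0,0,0,0,20
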