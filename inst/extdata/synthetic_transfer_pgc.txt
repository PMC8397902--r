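# synthetic periglomerular cell transfer table: input (activity units), rate (spikes/s)
0 0
0.25 0
0.5 0
0.75 2.0559
1 5.462
1.25 8.8132
1.5 12.0778
1.75 15.2274
2 18.2376
2.25 21.0889
2.5 23.7671
2.75 26.2626
3 28.5706
3.25 30.6908
3.5 32.626
3.75 34.3823
4 35.9679
4.25 37.3927
4.5 38.6675
4.75 39.8038
5 40.8132
5.25 41.7072
5.5 42.4969
5.75 43.1928
6 43.8048
6.25 44.342
6.5 44.8128
6.75 45.2248
7 45.5849
7.25 45.8994
7.5 46.1737
7.75 46.4128
8 46.6211
8.25 46.8023
8.5 46.9601
8.75 47.0972
9 47.2164
9.25 47.32
9.5 47.4099
9.75 47.4881
10 47.5559
10.25 47.6148
10.5 47.6659
10.75 47.7102
11 47.7487
11.25 47.7821
11.5 47.811
11.75 47.8361
12 47.8579
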