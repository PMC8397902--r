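# synthetic granule cell transfer table: input (activity units), rate (spikes/s)
0 0
0.25 0
0.5 0
0.75 0
1 0
1.25 0
1.5 0
1.75 1.332
2 2.6557
2.25 3.9634
2.5 5.2472
2.75 6.5003
3 7.7163
3.25 8.8896
3.5 10.0157
3.75 11.0908
4 12.1121
4.25 13.0778
4.5 13.9868
4.75 14.8388
5 15.6343
5.25 16.3743
5.5 17.0603
5.75 17.6942
6 18.2783
6.25 18.815
6.5 19.3069
6.75 19.7568
7 20.1674
7.25 20.5414
7.5 20.8815
7.75 21.1902
8 21.4701
8.25 21.7236
8.5 21.9527
8.75 22.1598
9 22.3466
9.25 22.5151
9.5 22.6669
9.75 22.8036
10 22.9266
10.25 23.0372
10.5 23.1367
10.75 23.226
11 23.3062
11.25 23.3782
11.5 23.4428
11.75 23.5008
12 23.5528
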