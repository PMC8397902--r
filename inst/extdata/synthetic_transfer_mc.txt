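# synthetic mitral cell transfer table: input (activity units), rate (spikes/s)
0 0
0.25 0
0.5 0
0.75 0
1 0
1.25 2.4967
1.5 4.9741
1.75 7.4133
2 9.7967
2.25 12.1084
2.5 14.3343
2.75 16.4628
3 18.4847
3.25 20.3932
3.5 22.184
3.75 23.8549
4 25.406
4.25 26.8387
4.5 28.1562
4.75 29.3629
5 30.4638
5.25 31.4648
5.5 32.372
5.75 33.1921
6 33.9313
6.25 34.5963
6.5 35.1931
6.75 35.7277
7 36.2059
7.25 36.633
7.5 37.0138
7.75 37.3531
8 37.655
8.25 37.9234
8.5 38.1618
8.75 38.3734
9 38.5611
9.25 38.7275
9.5 38.8749
9.75 39.0055
10 39.121
10.25 39.2233
10.5 39.3138
10.75 39.3938
11 39.4646
11.25 39.5271
11.5 39.5824
11.75 39.6312
12 39.6744
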