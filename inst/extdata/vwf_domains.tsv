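label	start_aa	end_aa
SP	1	22
D1	23	385
D2	386	763
D'	764	865
D3	866	1270
A1	1271	1493
A2	1494	1671
A3	1672	1874
D4	1875	2255
C1	2256	2328
C2	2329	2399
C3	2400	2516
C4	2517	2577
C5	2578	2646
C6	2647	2722
CK	2723	2813
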