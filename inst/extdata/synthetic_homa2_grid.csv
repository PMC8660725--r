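glucose,cpeptide,homa2_b,homa2_ir
3.00,0.0662,27.002993763,0.1039164508
3.00,0.3000,122.370062370,0.4709204720
3.00,0.7600,310.004158004,1.1929985290
3.00,1.1585,472.552390852,1.8185378892
4.50,0.0662,13.240000000,0.1324000000
6.00,0.0662,8.422952183,0.1566147244
6.00,0.3000,38.170478170,0.7097344004
6.00,0.7600,96.698544699,1.7979938144
6.00,1.1585,147.401663202,2.7407576763
8.00,0.0662,5.713362786,0.1841998821
10.77,0.0662,4.151795908,0.2174361473
10.77,0.3000,18.814785081,0.9853601840
10.77,0.7600,47.664122205,2.4962457993
10.77,1.1585,72.656428387,3.8051325770
14.00,0.0662,3.367158556,0.2551042713
18.00,0.0662,2.917754678,0.2970839850
18.00,0.3000,13.222453222,1.3463020469
18.00,0.7600,33.496881497,3.4106318522
18.00,1.1585,51.060706861,5.1989697379
22.00,0.0662,2.690267178,0.3359062151
25.00,0.0662,2.586341788,0.3638115628
25.00,0.3000,11.720582121,1.6486928829
25.00,0.7600,29.692141372,4.1766886367
25.00,1.1585,45.260981289,6.3667023494
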