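patient_id,cmax_pf,cmax_pl,t_half_pf,t_half_pl,auc90_pf,auc90_pl,auc_total_pl,auc_ratio
1,365,23,123,131,25865,1572,5361,16.5
2,349,27,92,153,22920,1956,6427,11.7
3,279,21,190,170,21643,1431,5120,15.1
4,595,39,63,162,34122,2695,10028,12.7
5,360,32,102,170,24953,2032,8805,12.3
6,407,27,132,173,28909,1682,6451,17.2
7,290,32,106,140,19956,2162,6449,9.2
8,293,29,115,181,20967,1955,8014,10.7
9,297,33,108,147,20667,2134,7330,9.7
10,322,29,96,164,21813,1928,6936,11.3
11,393,29,109,154,26916,1928,6328,14.0
12,400,28,112,182,28384,1746,7310,16.3
13,354,28,98,193,24304,1794,6865,13.5
14,297,32,76,157,17671,2384,7662,7.4
15,318,27,90,134,20225,1828,5850,11.1
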