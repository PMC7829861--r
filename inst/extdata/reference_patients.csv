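patient_id,crs_timing,pci,peritonectomy,duration_surgery_min,bleeding_ml,perfusate_volume_abdomen,bsa,dose
1,interval,8,minor,317,1700,2.0,2.02,1600
2,upfront,12,major,300,750,3.8,1.92,1536
3,interval,5,minor,360,1700,1.8,1.42,1136
4,interval,8,minor,397,500,3.9,2.16,1600
5,interval,22,major,416,1300,2.1,1.76,1408
6,interval,8,minor,315,500,2.5,1.93,1544
7,upfront,17,major,427,1000,2.4,1.60,1280
8,upfront,15,minor,301,770,3.3,1.65,1320
9,interval,8,minor,450,500,3.0,1.78,1424
10,interval,12,major,321,400,3.4,1.82,1456
11,upfront,16,major,346,1000,3.0,1.95,1560
12,interval,18,major,390,1500,2.1,2.05,1600
13,interval,3,minor,312,500,2.0,2.10,1600
14,interval,6,minor,311,650,3.4,1.63,1296
15,interval,8,minor,260,250,3.1,1.64,1312
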