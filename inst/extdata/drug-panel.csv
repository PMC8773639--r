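condition,ratio,time_h,channel,count,replicate
heterotypic-cisplatin-continuous,1,0,red,2677.38,1
heterotypic-cisplatin-continuous,1,12,red,3842.274,1
heterotypic-cisplatin-continuous,1,24,red,6192.971,1
heterotypic-cisplatin-continuous,1,36,red,9287.548,1
heterotypic-cisplatin-continuous,1,48,red,12841.209,1
heterotypic-cisplatin-continuous,1,60,red,16156.763,1
heterotypic-cisplatin-continuous,1,72,red,20204.881,1
heterotypic-cisplatin-continuous,1,84,red,18426.236,1
heterotypic-cisplatin-continuous,1,96,red,16464.191,1
heterotypic-cisplatin-continuous,1,108,red,9146.249,1
heterotypic-cisplatin-continuous,1,120,red,4358.933,1
heterotypic-cisplatin-continuous,1,132,red,1397.752,1
heterotypic-cisplatin-continuous,1,144,red,236.114,1
heterotypic-cisplatin-continuous,1,0,green,2465.393,1
heterotypic-cisplatin-continuous,1,12,green,3838.518,1
heterotypic-cisplatin-continuous,1,24,green,5908.856,1
heterotypic-cisplatin-continuous,1,36,green,7848.139,1
heterotypic-cisplatin-continuous,1,48,green,8849.49,1
heterotypic-cisplatin-continuous,1,60,green,10004.102,1
heterotypic-cisplatin-continuous,1,72,green,11419.559,1
heterotypic-cisplatin-continuous,1,84,green,8097.734,1
heterotypic-cisplatin-continuous,1,96,green,4570.208,1
heterotypic-cisplatin-continuous,1,108,green,2342.937,1
heterotypic-cisplatin-continuous,1,120,green,920.962,1
heterotypic-cisplatin-continuous,1,132,green,270.047,1
heterotypic-cisplatin-continuous,1,144,green,52.357,1
heterotypic-cisplatin-intermittent,1,0,red,2468.047,1
heterotypic-cisplatin-intermittent,1,12,red,3618.795,1
heterotypic-cisplatin-intermittent,1,24,red,6223.07,1
heterotypic-cisplatin-intermittent,1,36,red,8714.879,1
heterotypic-cisplatin-intermittent,1,48,red,12874.113,1
heterotypic-cisplatin-intermittent,1,60,red,17595.031,1
heterotypic-cisplatin-intermittent,1,72,red,24144.546,1
heterotypic-cisplatin-intermittent,1,84,red,30017.654,1
heterotypic-cisplatin-intermittent,1,96,red,42837.266,1
heterotypic-cisplatin-intermittent,1,108,red,51740.4,1
heterotypic-cisplatin-intermittent,1,120,red,73170.699,1
heterotypic-cisplatin-intermittent,1,132,red,98435.478,1
heterotypic-cisplatin-intermittent,1,144,red,122874.678,1
heterotypic-cisplatin-intermittent,1,0,green,2504.519,1
heterotypic-cisplatin-intermittent,1,12,green,3904.198,1
heterotypic-cisplatin-intermittent,1,24,green,5621.519,1
heterotypic-cisplatin-intermittent,1,36,green,8268.038,1
heterotypic-cisplatin-intermittent,1,48,green,9745.907,1
heterotypic-cisplatin-intermittent,1,60,green,10863.614,1
heterotypic-cisplatin-intermittent,1,72,green,12368.526,1
heterotypic-cisplatin-intermittent,1,84,green,10552.268,1
heterotypic-cisplatin-intermittent,1,96,green,8922.353,1
heterotypic-cisplatin-intermittent,1,108,green,4787.149,1
heterotypic-cisplatin-intermittent,1,120,green,2130.395,1
heterotypic-cisplatin-intermittent,1,132,green,561.742,1
heterotypic-cisplatin-intermittent,1,144,green,77.39,1
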