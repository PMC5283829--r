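cx_um,cy_um,r_um
4040.62598081259,173.142596803616,154.111322180501
702.152612228813,206.452824498922,87.8370518098065
1063.79633872526,267.521575273651,94.9541961880021
1960.0527032066,328.59032604838,179.827939955479
2494.66534119148,328.59032604838,150.710008107374
2856.30906768793,389.659076823109,119.00982428786
3752.56543216926,450.727827597838,142.762428858421
1310.34842806682,545.106806067874,96.6703120601039
2206.60479254816,606.175556842603,179.337852693758
2568.24851904461,667.244307617332,115.888477722856
3102.86115702949,667.244307617332,102.896615252642
3464.50488352594,728.313058392061,148.862130708912
3999.11752151082,728.313058392061,105.092360614638
126.031514942166,761.623286087367,102.183189379894
1022.2878794235,822.692036862096,165.132683854229
1918.54424390483,883.760787636825,108.404340328542
2814.80060838617,944.829538411555,163.831936261828
4072.70069936395,1066.96703996101,169.075254281511
734.227330780176,1100.27726765632,156.64236100604
1630.48369526151,1161.34601843105,88.3871125989228
2526.74005974284,1222.41476920578,179.153806744012
3422.99642422418,1283.48351998051,139.494643905219
3784.64015072063,1344.55227075524,101.4684212826
4319.25278870551,1344.55227075524,165.019704113764
1342.42314661819,1438.93124922527,90.9566559115654
2238.67951109952,1500,120.004214155601
3134.93587558085,1561.06875077473,182.304227844792
3496.5796020773,1622.13750154946,88.9076222902122
4031.19224006219,1622.13750154946,112.163160317592
158.106233493529,1655.44772924476,92.0859825880046
692.718871478412,1655.44772924476,149.268727508627
1054.36259797486,1716.51648001949,122.512658233392
1588.97523595975,1716.51648001949,134.375355275681
1950.6189624562,1777.58523079422,121.114316807462
2846.87532693753,1838.65398156895,184.959226329734
3743.13169141886,1899.72273234368,155.736041590188
4104.77541791531,1960.79148311841,80.9561314021268
404.658322835088,1933.03296003899,160.564825987413
766.302049331539,1994.10171081372,151.207415914814
1300.91468731642,1994.10171081372,105.574049661743
1662.55841381287,2055.17046158845,90.8724986426471
2558.81477829421,2116.23921236317,143.944685412597
3455.07114277554,2177.3079631379,159.762668977103
116.597774191765,2210.61819083321,90.8304028916279
478.241500688216,2271.68694160794,130.869332880233
1012.8541386731,2271.68694160794,172.737114359107
2805.36686763576,2393.8244431574,165.115148537396
3167.01059413222,2454.89319393213,113.770907776225
724.793590029775,2549.27217240216,185.742048962605
1086.43731652623,2610.34092317689,122.498182300103
1621.04995451111,2610.34092317689,162.482494027626
2517.30631899244,2671.40967395162,160.494355989134
2878.95004548889,2732.47842472635,141.941264195529
3413.56268347377,2732.47842472635,106.051843837857
436.733041386452,2826.85740319638,113.367565649893
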