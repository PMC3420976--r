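# half_size_m: 0.04
# speed_m_s: 2
t_rel_s,rate
-1.5000000000000000,10.66144326318750
-1.4900000000000000,9.80727078586052
-1.4800000000000000,11.03582882566032
-1.4700000000000000,9.48308561302735
-1.4600000000000000,9.96179621151526
-1.4500000000000000,10.51021002107853
-1.4399999999999999,8.76871041786343
-1.4299999999999999,9.83403590099874
-1.4199999999999999,10.07443279890954
-1.4099999999999999,10.05756901628222
-1.3999999999999999,10.36758061473987
-1.3899999999999999,10.33355554214725
-1.3799999999999999,10.11830127227194
-1.3700000000000001,11.17514989086957
-1.3599999999999999,9.71767038029791
-1.3500000000000001,10.32373228184769
-1.3400000000000001,11.10626712041151
-1.3300000000000001,10.64573993179424
-1.3200000000000001,10.62433796003978
-1.3100000000000001,10.91878893457129
-1.3000000000000000,10.87876649802601
-1.2900000000000000,10.71569326511258
-1.2800000000000000,11.22806582952478
-1.2700000000000000,11.08207427510382
-1.2600000000000000,10.79371930819542
-1.2500000000000000,10.16457247189939
-1.2400000000000000,10.69099097638655
-1.2300000000000000,10.43331916173174
-1.2200000000000000,9.74192013711161
-1.2100000000000000,10.82574184758442
-1.2000000000000000,11.09905801913021
-1.1899999999999999,12.17013321727755
-1.1799999999999999,12.20993217630291
-1.1699999999999999,12.01554808915540
-1.1599999999999999,10.81431065389089
-1.1499999999999999,10.43115309175250
-1.1400000000000001,11.03350844697379
-1.1299999999999999,12.34764990311238
-1.1200000000000001,11.73882918427425
-1.1099999999999999,12.00179064811092
-1.1000000000000001,11.33640450414311
-1.0899999999999999,10.97216268384926
-1.0800000000000001,12.29248019077895
-1.0700000000000001,11.81089875990116
-1.0600000000000001,11.47376564205248
-1.0500000000000000,12.19588552176264
-1.0400000000000000,12.80475508537428
-1.0300000000000000,12.88978217031278
-1.0200000000000000,13.06700485706342
-1.0100000000000000,12.27686648531534
-1.0000000000000000,13.29714635240901
-0.9900000000000000,12.67607220368129
-0.9800000000000000,12.91159769794575
-0.9700000000000000,13.74725006272782
-0.9600000000000000,13.46131211940294
-0.9500000000000000,13.12682931893938
-0.9399999999999999,14.07348998338411
-0.9299999999999999,13.03457223078326
-0.9200000000000000,12.87029021433265
-0.9100000000000000,13.77912580081682
-0.9000000000000000,13.69697571641166
-0.8900000000000000,13.73371478279964
-0.8800000000000000,13.64275843502965
-0.8700000000000000,13.42966843349894
-0.8600000000000000,15.02962369630193
-0.8500000000000000,13.13410852188490
-0.8400000000000000,15.31443705568096
-0.8300000000000000,13.84188647187999
-0.8200000000000000,15.45394724550113
-0.8099999999999999,13.96148974901232
-0.7999999999999999,15.61132976613942
-0.7900000000000000,14.78722367666329
-0.7800000000000000,16.24219121321561
-0.7700000000000000,15.12959346432122
-0.7600000000000000,16.75109638320938
-0.7500000000000000,16.37868034928529
-0.7400000000000000,16.15667785793162
-0.7300000000000000,16.11632415233383
-0.7200000000000000,15.59298489708895
-0.7100000000000000,16.94586585318747
-0.7000000000000000,17.01350114618009
-0.6899999999999999,19.16107574914408
-0.6799999999999999,17.83901659581030
-0.6699999999999999,18.11935217004772
-0.6600000000000000,18.50490765981552
-0.6500000000000000,18.04680428741653
-0.6400000000000000,18.93047541501240
-0.6300000000000000,19.41089291384770
-0.6200000000000000,20.84675073521781
-0.6100000000000000,21.46983312355874
-0.6000000000000000,22.67064851379808
-0.5900000000000000,18.77502597663226
-0.5800000000000000,21.84586616838988
-0.5700000000000000,21.46755295783748
-0.5599999999999999,22.10065747044892
-0.5499999999999999,22.97594238838296
-0.5400000000000000,24.69033983445081
-0.5300000000000000,25.05992972737222
-0.5200000000000000,23.61178308030861
-0.5100000000000000,25.14712254514039
-0.5000000000000000,26.30783305611071
-0.4900000000000000,26.00044656575506
-0.4800000000000000,28.67421886565670
-0.4700000000000000,28.78073909509069
-0.4600000000000000,29.93707318356264
-0.4500000000000000,29.67082627025730
-0.4399999999999999,30.27648735380807
-0.4299999999999999,30.75753788742823
-0.4199999999999999,33.40032026544615
-0.4099999999999999,31.09415223787961
-0.3999999999999999,36.33701242197026
-0.3899999999999999,39.28393568038487
-0.3799999999999999,35.78655907987898
-0.3699999999999999,36.05364119886980
-0.3599999999999999,39.50525383847616
-0.3499999999999999,40.49509062173219
-0.3400000000000001,41.12378331806020
-0.3300000000000001,50.89038939182741
-0.3200000000000001,48.49061959782001
-0.3100000000000001,50.17007454539675
-0.3000000000000000,55.82652746867968
-0.2900000000000000,57.50564577963317
-0.2800000000000000,63.07372833854403
-0.2700000000000000,68.59870188106764
-0.2600000000000000,70.07834558351252
-0.2500000000000000,72.96763754598237
-0.2400000000000000,79.06397344934214
-0.2300000000000000,74.46447519131523
-0.2200000000000000,84.75951426262304
-0.2100000000000000,89.74688436514606
-0.2000000000000000,96.40320795667989
-0.1899999999999999,117.01772810558387
-0.1799999999999999,111.23432503182437
-0.1699999999999999,142.31236914949503
-0.1599999999999999,133.18883858105119
-0.1499999999999999,154.01156130775476
-0.1399999999999999,169.68508819633308
-0.1299999999999999,197.90245240113373
-0.1199999999999999,205.67108593995073
-0.1099999999999999,254.76490343424121
-0.0999999999999999,268.66189808442869
-0.0900000000000001,300.14637392838654
-0.0800000000000001,344.24204322995661
-0.0700000000000001,395.10076310316850
-0.0600000000000001,378.91703886816242
-0.0500000000000000,360.91251449368769
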