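region,year,dimension,grade,fitted_rsr
Fujian,2009,needs,Low,0.046
Xizang,2009,utilization,Low,0.399
Jiangsu,2009,resources,Low,0.102
Zhejiang,2009,needs,Low,0.089
Anhui,2009,utilization,Low,0.444
Guizhou,2009,resources,Low,0.17
Beijing,2009,needs,Low,0.118
Hainan,2009,utilization,Low,0.473
Anhui,2009,resources,Low,0.143
Tianjin,2009,needs,Low,0.14
Qinghai,2009,utilization,Low,0.496
Chongqing,2009,resources,Low,0.192
Shaanxi,2009,needs,Medium,0.159
Guizhou,2009,utilization,Medium,0.515
Sichuan,2009,resources,Medium,0.209
Hunan,2009,needs,Medium,0.175
Shanxi,2009,utilization,Medium,0.532
Liaoning,2009,resources,Medium,0.225
Liaoning,2009,needs,Medium,0.19
Jilin,2009,utilization,Medium,0.548
Yunnan,2009,resources,Medium,0.239
Guangxi,2009,needs,Medium,0.204
Chongqing,2009,utilization,Medium,0.562
Shanghai,2009,resources,Medium,0.252
Shandong,2009,needs,Medium,0.217
Shanghai,2009,utilization,Medium,0.575
Fujian,2009,resources,Medium,0.264
Jiangsu,2009,needs,Medium,0.229
Xinjiang,2009,utilization,Medium,0.587
Qinghai,2009,resources,Medium,0.276
Shanxi,2009,needs,Medium,0.24
Sichuan,2009,utilization,Medium,0.599
Shandong,2009,resources,Medium,0.287
Ningxia,2009,needs,Medium,0.252
Gansu,2009,utilization,Medium,0.611
Henan,2009,resources,Medium,0.297
Jilin,2009,needs,Medium,0.263
Jiangxi,2009,utilization,Medium,0.622
Heilongjiang,2009,resources,Medium,0.308
Henan,2009,needs,Medium,0.274
Yunnan,2009,utilization,Medium,0.633
Hunan,2009,resources,Medium,0.318
Guangdong,2009,needs,Medium,0.284
Heilongjiang,2009,utilization,Medium,0.644
Hubei,2009,resources,Medium,0.328
Inner Mongolia,2009,needs,Medium,0.295
Hunan,2009,utilization,Medium,0.655
Jiangxi,2009,resources,Medium,0.338
Jiangxi,2009,needs,Medium,0.306
Hebei,2009,utilization,Medium,0.666
Gansu,2009,resources,Medium,0.349
Hubei,2009,needs,Medium,0.316
Guangdong,2009,utilization,Medium,0.677
Tianjin,2009,resources,Medium,0.359
Hebei,2009,needs,Medium,0.327
Fujian,2009,utilization,Medium,0.689
Hebei,2009,resources,Medium,0.369
Gansu,2009,needs,Medium,0.339
Tianjin,2009,utilization,Medium,0.7
Hainan,2009,resources,Medium,0.38
Anhui,2009,needs,Medium,0.35
Inner Mongolia,2009,utilization,Medium,0.712
Shaanxi,2009,resources,Medium,0.391
Heilongjiang,2009,needs,Medium,0.362
Hubei,2009,utilization,Medium,0.725
Jilin,2009,resources,Medium,0.402
Hainan,2009,needs,Medium,0.375
Guangxi,2009,utilization,Medium,0.738
Guangxi,2009,resources,Medium,0.415
Shanghai,2009,needs,Medium,0.389
Henan,2009,utilization,Medium,0.752
Guangdong,2009,resources,Medium,0.428
Sichuan,2009,needs,Medium,0.404
Shaanxi,2009,utilization,Medium,0.767
Xizang,2009,resources,Medium,0.442
Yunnan,2009,needs,Medium,0.42
Jiangsu,2009,utilization,Medium,0.784
Zhejiang,2009,resources,Medium,0.457
Guizhou,2009,needs,High,0.439
Ningxia,2009,utilization,High,0.803
Shanxi,2009,resources,High,0.475
Chongqing,2009,needs,High,0.461
Liaoning,2009,utilization,High,0.826
Inner Mongolia,2009,resources,High,0.496
Xinjiang,2009,needs,High,0.49
Shandong,2009,utilization,High,0.856
Xinjiang,2009,resources,High,0.523
Qinghai,2009,needs,High,0.534
Zhejiang,2009,utilization,High,0.901
Ningxia,2009,resources,High,0.565
Xizang,2009,needs,High,0.607
Beijing,2009,utilization,High,0.976
Beijing,2009,resources,High,0.635
Beijing,2019,needs,Low,0.035
Xizang,2019,utilization,Low,0.637
Tianjin,2019,resources,Low,0.122
Shanghai,2019,needs,Low,0.077
Ningxia,2019,utilization,Low,0.674
Shanghai,2019,resources,Low,0.165
Hainan,2019,needs,Low,0.104
Henan,2019,utilization,Low,0.699
Liaoning,2019,resources,Low,0.193
Guangdong,2019,needs,Low,0.125
Yunnan,2019,utilization,Low,0.718
Heilongjiang,2019,resources,Low,0.215
Chongqing,2019,needs,Medium,0.143
Shanxi,2019,utilization,Medium,0.734
Anhui,2019,resources,Medium,0.234
Hunan,2019,needs,Medium,0.159
Qinghai,2019,utilization,Medium,0.748
Jiangsu,2019,resources,Medium,0.25
Hebei,2019,needs,Medium,0.173
Xinjiang,2019,utilization,Medium,0.76
Jilin,2019,resources,Medium,0.265
Inner Mongolia,2019,needs,Medium,0.186
Jiangsu,2019,utilization,Medium,0.772
Chongqing,2019,resources,Medium,0.278
Guangxi,2019,needs,Medium,0.198
Hainan,2019,utilization,Medium,0.783
Shanxi,2019,resources,Medium,0.291
Shandong,2019,needs,Medium,0.209
Hebei,2019,utilization,Medium,0.793
Fujian,2019,resources,Medium,0.303
Shaanxi,2019,needs,Medium,0.22
Anhui,2019,utilization,Medium,0.803
Sichuan,2019,resources,Medium,0.314
Jiangsu,2019,needs,Medium,0.231
Guizhou,2019,utilization,Medium,0.813
Xinjiang,2019,resources,Medium,0.325
Anhui,2019,needs,Medium,0.241
Beijing,2019,utilization,Medium,0.822
Jiangxi,2019,resources,Medium,0.336
Hubei,2019,needs,Medium,0.252
Gansu,2019,utilization,Medium,0.832
Hebei,2019,resources,Medium,0.347
Jiangxi,2019,needs,Medium,0.262
Shandong,2019,utilization,Medium,0.841
Henan,2019,resources,Medium,0.357
Fujian,2019,needs,Medium,0.272
Fujian,2019,utilization,Medium,0.85
Beijing,2019,resources,Medium,0.368
Shanxi,2019,needs,Medium,0.282
Chongqing,2019,utilization,Medium,0.859
Hainan,2019,resources,Medium,0.379
Zhejiang,2019,needs,Medium,0.292
Liaoning,2019,utilization,Medium,0.868
Shandong,2019,resources,Medium,0.389
Henan,2019,needs,Medium,0.303
Guangdong,2019,utilization,Medium,0.878
Hubei,2019,resources,Medium,0.4
Gansu,2019,needs,Medium,0.314
Heilongjiang,2019,utilization,Medium,0.888
Guangdong,2019,resources,Medium,0.411
Guizhou,2019,needs,Medium,0.325
Sichuan,2019,utilization,Medium,0.897
Gansu,2019,resources,Medium,0.423
Jilin,2019,needs,Medium,0.336
Jiangxi,2019,utilization,Medium,0.908
Shaanxi,2019,resources,Medium,0.435
Sichuan,2019,needs,Medium,0.348
Hubei,2019,utilization,Medium,0.919
Yunnan,2019,resources,Medium,0.447
Xinjiang,2019,needs,Medium,0.361
Shaanxi,2019,utilization,Medium,0.93
Hunan,2019,resources,Medium,0.461
Liaoning,2019,needs,Medium,0.375
Inner Mongolia,2019,utilization,Medium,0.943
Inner Mongolia,2019,resources,Medium,0.475
Yunnan,2019,needs,Medium,0.391
Jilin,2019,utilization,Medium,0.957
Zhejiang,2019,resources,Medium,0.492
Heilongjiang,2019,needs,High,0.409
Hunan,2019,utilization,High,0.973
Guangxi,2019,resources,High,0.51
Ningxia,2019,needs,High,0.43
Shanghai,2019,utilization,High,0.992
Xizang,2019,resources,High,0.532
Qinghai,2019,needs,High,0.457
Guangxi,2019,utilization,High,1.017
Qinghai,2019,resources,High,0.561
Tianjin,2019,needs,High,0.499
Tianjin,2019,utilization,High,1.054
Ningxia,2019,resources,High,0.604
Xizang,2019,needs,High,0.569
Zhejiang,2019,utilization,High,1.117
Guizhou,2019,resources,High,0.676
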