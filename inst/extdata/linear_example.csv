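,dim1,dim2
cell1,0.0409,0.0249
cell2,0.0327,-0.0016
cell3,0.0400,0.0016
cell4,0.0646,0.0347
cell5,0.0428,0.0132
cell6,0.0710,0.0560
cell7,0.0142,0.0556
cell8,0.0378,0.0368
cell9,0.0580,0.0476
cell10,0.0701,0.0361
cell11,0.0618,0.0567
cell12,0.1171,0.0550
cell13,0.0857,0.0910
cell14,0.1373,0.0995
cell15,0.0875,0.0870
cell16,0.1558,0.1352
cell17,0.1718,0.0794
cell18,0.1219,0.0624
cell19,0.1283,0.0989
cell20,0.1576,0.1071
cell21,0.1171,0.0682
cell22,0.1130,0.1147
cell23,0.1898,0.0969
cell24,0.1884,0.1145
cell25,0.1726,0.1049
cell26,0.1779,0.1330
cell27,0.2004,0.0874
cell28,0.1778,0.1246
cell29,0.1855,0.1167
cell30,0.1895,0.1220
cell31,0.2189,0.1288
cell32,0.2412,0.0995
cell33,0.2389,0.1438
cell34,0.2579,0.1217
cell35,0.2964,0.1947
cell36,0.2758,0.1424
cell37,0.2625,0.1532
cell38,0.2975,0.1549
cell39,0.2842,0.1327
cell40,0.3354,0.1574
cell41,0.3146,0.1850
cell42,0.3284,0.1710
cell43,0.3060,0.1690
cell44,0.2755,0.1876
cell45,0.3755,0.1880
cell46,0.3410,0.2178
cell47,0.3494,0.1843
cell48,0.3428,0.1692
cell49,0.3933,0.1601
cell50,0.4066,0.1809
cell51,0.4012,0.1873
cell52,0.4461,0.1989
cell53,0.4413,0.1476
cell54,0.4493,0.2307
cell55,0.4315,0.2038
cell56,0.4357,0.2158
cell57,0.4759,0.1954
cell58,0.4674,0.1843
cell59,0.4886,0.1863
cell60,0.4413,0.1885
cell61,0.4753,0.2233
cell62,0.4573,0.1892
cell63,0.4533,0.2357
cell64,0.5036,0.1656
cell65,0.5272,0.2015
cell66,0.5052,0.1792
cell67,0.5689,0.2071
cell68,0.5749,0.1964
cell69,0.5037,0.2126
cell70,0.5889,0.1964
cell71,0.5349,0.2239
cell72,0.5723,0.1961
cell73,0.5775,0.1707
cell74,0.5639,0.2214
cell75,0.5653,0.2010
cell76,0.6241,0.1805
cell77,0.6238,0.2237
cell78,0.6304,0.2436
cell79,0.5979,0.1857
cell80,0.6424,0.1846
cell81,0.6073,0.1901
cell82,0.6270,0.2129
cell83,0.6662,0.1533
cell84,0.6603,0.1529
cell85,0.6387,0.1375
cell86,0.6169,0.2154
cell87,0.6710,0.1591
cell88,0.6891,0.1754
cell89,0.7013,0.1277
cell90,0.7259,0.1287
cell91,0.7133,0.1316
cell92,0.7550,0.1944
cell93,0.7595,0.1687
cell94,0.7539,0.1247
cell95,0.7538,0.1355
cell96,0.7494,0.1174
cell97,0.7752,0.1237
cell98,0.7698,0.1135
cell99,0.7724,0.1109
cell100,0.8193,0.0792
cell101,0.8545,0.0748
cell102,0.8699,0.0911
cell103,0.8262,0.1006
cell104,0.8646,0.0806
cell105,0.8769,0.1162
cell106,0.8932,0.0701
cell107,0.8682,0.0528
cell108,0.9424,0.0778
cell109,0.9379,0.0966
cell110,0.9164,0.0266
cell111,0.9760,0.0135
cell112,0.9606,-0.0062
cell113,0.9273,0.0682
cell114,0.9605,0.0357
cell115,0.9636,0.0112
cell116,0.9738,0.0039
cell117,1.0029,-0.0085
cell118,0.9685,0.0165
cell119,0.9899,0.0264
cell120,1.0110,-0.0529
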