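country,ci_2019,rank_2019,tier_2019,ci_2021,rank_2021,tier_2021,ci_total,rank_total,tier_total,rank_shift,tier_shift
Austria,6.123,17,2,3.910,15,2,4.969,15,2,2,0
Belgium,7.979,10,1,4.637,12,1,6.210,10,1,-2,0
Bulgaria,8.280,8,1,4.886,10,1,6.502,9,1,-2,0
Croatia,4.894,23,2,3.002,23,2,3.881,23,2,0,0
Cyprus,2.280,26,3,1.864,26,3,1.933,26,3,0,0
Czech Republic,5.963,18,2,3.419,22,2,4.711,19,2,-4,0
Denmark,9.581,3,1,5.489,5,1,7.426,3,1,-2,0
Estonia,6.157,16,2,3.890,16,2,4.932,16,2,0,0
Finland,10.442,1,1,6.275,1,1,8.262,1,1,0,0
France,7.745,11,1,4.740,11,1,6.189,11,1,0,0
Germany,9.250,5,1,5.571,3,1,7.319,4,1,2,0
Greece,5.617,21,2,3.473,21,2,4.483,21,2,0,0
Hungary,6.169,15,2,3.776,18,2,4.887,17,2,-3,0
Ireland,6.299,14,2,4.037,13,2,5.129,14,2,1,0
Italy,5.841,19,2,3.622,20,2,4.644,20,2,-1,0
Latvia,8.598,7,1,5.502,4,1,7.042,6,1,3,0
Lithuania,6.912,13,2,4.944,9,1,5.969,12,1,4,1
Luxembourg,3.935,24,3,2.523,25,3,3.148,24,3,-1,0
Malta,1.025,27,3,1.109,27,3,1.085,27,3,0,0
Netherlands,9.516,4,1,5.360,6,1,7.289,5,1,-2,0
Poland,5.633,20,2,3.951,14,2,4.795,18,2,6,0
Portugal,6.984,12,2,3.801,17,2,5.231,13,2,-5,0
Romania,3.736,25,3,2.587,24,3,3.117,25,3,1,0
Slovakia,5.083,22,2,3.767,19,2,4.473,22,2,3,0
Slovenia,9.853,2,1,6.140,2,1,7.965,2,1,0,0
Spain,8.116,9,1,5.164,8,1,6.603,8,1,1,0
Sweden,8.953,6,1,5.236,7,1,6.999,7,1,-1,0
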