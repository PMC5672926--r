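cancer,dep,males_n,males_mean,males_total,females_n,females_mean,females_total
lung,1,2525,12.84,32416,2088,14.42,30112
lung,2,3437,12.31,42315,2700,14.17,38268
lung,3,3883,12.29,47728,3238,13.82,44750
lung,4,4292,11.89,51042,3668,13.78,50538
lung,5,4737,11.81,55952,4100,13.82,56648
stomach,1,593,11.6,6882,305,12.63,3852
stomach,2,720,10.51,7567,323,12.59,4068
stomach,3,729,10.99,8012,378,11.75,4442
stomach,4,741,10.4,7705,432,11.44,4942
stomach,5,746,10.52,7848,387,11.84,4583
ovarian,1,,,,1161,12.37,14356
ovarian,2,,,,1248,11.91,14864
ovarian,3,,,,1208,11.51,13906
ovarian,4,,,,1083,11.15,12073
ovarian,5,,,,945,10.62,10035
bladder,1,1260,6.04,7605,386,7.49,2892
bladder,2,1348,5.44,7330,448,7.35,3294
bladder,3,1332,5.58,7438,442,7.61,3364
bladder,4,1123,5.58,6262,466,7.73,3604
bladder,5,975,5.61,5466,424,8.11,3439
colon,1,2430,6.67,16205,2053,7.15,14683
colon,2,2443,6.37,15553,2217,6.67,14783
colon,3,2324,6.34,14738,2065,7.02,14501
colon,4,2039,6.34,12929,1845,7.1,13102
colon,5,1708,6.84,11687,1483,7.73,11467
rectum,1,1464,6.97,10200,790,7.18,5673
rectum,2,1499,6.84,10256,816,6.88,5612
rectum,3,1395,6.86,9568,843,7.25,6114
rectum,4,1245,6.79,8456,779,7.19,5601
rectum,5,1158,7.26,8402,642,7.96,5110
breast,1,,,,9452,5.39,50981
breast,2,,,,9154,5.28,48303
breast,3,,,,8529,5.3,45226
breast,4,,,,7410,5.6,41494
breast,5,,,,6054,6.01,36394
melanoma,1,1564,3.79,5929,1578,2.85,4500
melanoma,2,1425,3.79,5400,1423,2.78,3953
melanoma,3,1263,3.88,4906,1243,2.78,3460
melanoma,4,908,3.97,3603,1018,3.15,3206
melanoma,5,547,4.42,2418,617,3.06,1887
prostate,1,9651,3.04,29335,,,
prostate,2,9716,2.88,28003,,,
prostate,3,8343,2.81,23484,,,
prostate,4,6620,2.58,17111,,,
prostate,5,5326,2.39,12725,,,
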