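species,mc1,mc2,mc3,mc4,mc5,brain,neocortex,cerebellum,tool_any,tool_true,tool_manufacture,tool_single_individual,tool_captive_only,is_hominin,is_extant
t1,40.9001,40.859,66.8677,60.4129,25.1222,25.2949,24.6675,5.4421,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t2,14.0743,10.7298,11.6699,15.0779,6.6472,153.7095,13.7572,9.6125,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,TRUE
t3,22.9116,20.4889,21.1528,14.8154,21.2729,27.863,43.6147,14.4266,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t4,26.2415,23.4347,23.8293,21.2309,21.7231,37.9853,32.2183,22.7763,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t5,31.2944,22.9065,15.9497,17.4991,22.7136,119.0368,6.2856,4.9707,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t6,12.9277,11.7172,14.4238,14.9016,7.7819,10.9717,22.3461,25.4279,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t7,46.0379,47.6448,42.8794,36.8879,39.7181,33.6524,10.8688,14.442,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t8,29.9454,22.5139,15.6254,17.1343,19.2232,85.7895,9.0931,6.4655,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t9,46.0537,35.7483,28.006,28.0953,28.9221,105.7944,6.9039,8.0148,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t10,27.093,23.2476,24.233,20.9702,21.7486,36.0093,34.5461,23.948,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t11,56.7498,48.098,53.8951,39.0934,49.3456,88.2019,13.008,3.5911,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t12,52.4794,36.222,36.2833,46.916,22.7149,313.6939,10.0314,12.1951,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE
t13,8.7012,8.2683,10.4923,9.3642,5.677,22.8548,48.1382,21.586,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t14,37.4003,27.7741,32.639,20.2532,32.6066,60.2748,15.8995,3.193,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t15,14.212,12.352,11.3669,10.8407,11.3256,18.7141,22.838,11.8725,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t16,15.3756,16.3887,15.3208,17.386,9.4568,7.8267,28.5606,22.3348,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t17,21.4693,22.4686,16.1539,16.4789,20.6326,23.478,33.333,20.7471,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t18,20.115,18.5034,13.5325,21.4453,18.8306,25.5618,13.0408,17.4278,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t19,16.738,16.7941,12.2019,11.4549,15.0372,17.4791,19.2983,17.4738,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
t20,23.01,17.3386,20.4168,23.6373,10.9838,179.0331,16.9379,6.654,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE
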