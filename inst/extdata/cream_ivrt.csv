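replicate,time_h,q_ug_per_cm2,layer,amount_ug,mass_mg
1,0.5,2.065841043,,,
1,1,4.628058397,,,
1,2,7.457137989,,,
1,4,16.04078503,,,
1,6,23.14335112,,,
1,8,33.45657446,,,
1,24,64.74418856,,,
2,0.5,2.132627829,,,
2,1,4.886706126,,,
2,2,7.976883783,,,
2,4,16.80518846,,,
2,6,19.62466403,,,
2,8,34.74741351,,,
2,24,47.4340876,,,
3,0.5,2.093559879,,,
3,1,4.140800671,,,
3,2,7.265199699,,,
3,4,15.67207404,,,
3,6,19.55795843,,,
3,8,20.68264653,,,
3,24,57.61105417,,,
4,0.5,2.410559284,,,
4,1,4.094952036,,,
4,2,6.629190588,,,
4,4,17.36061466,,,
4,6,17.9030021,,,
4,8,30.10835764,,,
4,24,57.99418537,,,
5,0.5,2.325342769,,,
5,1,4.590705754,,,
5,2,9.424806151,,,
5,4,16.1965687,,,
5,6,25.67944578,,,
5,8,20.61242854,,,
5,24,70.50103735,,,
6,0.5,1.946667296,,,
6,1,4.370101448,,,
6,2,9.460579953,,,
6,4,12.10734242,,,
6,6,23.62363559,,,
6,8,30.17756133,,,
6,24,66.1047964,,,
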