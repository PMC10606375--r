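replicate,time_h,q_ug_per_cm2,layer,amount_ug,mass_mg
1,12,3.865916274,,,
1,14,5.409188929,,,
1,16,6.36436318,,,
1,18,6.335607715,,,
1,20,8.775792152,,,
1,22,8.760232435,,,
1,24,9.125484623,,,
1,36,17.74393377,,,
2,12,4.441627359,,,
2,14,4.541681591,,,
2,16,6.642889135,,,
2,18,6.380017883,,,
2,20,8.147917394,,,
2,22,8.138635249,,,
2,24,8.992274048,,,
2,36,13.77377691,,,
3,12,4.86250165,,,
3,14,3.855350589,,,
3,16,4.831872332,,,
3,18,6.125912246,,,
3,20,6.903330253,,,
3,22,8.169231563,,,
3,24,8.520154079,,,
3,36,11.32088672,,,
4,12,4.625456468,,,
4,14,4.457692296,,,
4,16,4.846994186,,,
4,18,7.485795883,,,
4,20,6.184905569,,,
4,22,7.996282062,,,
4,24,11.18570241,,,
4,36,12.23008018,,,
5,12,3.706201312,,,
5,14,4.821187173,,,
5,16,6.315974772,,,
5,18,6.570193416,,,
5,20,6.828375991,,,
5,22,8.795079329,,,
5,24,10.87116965,,,
5,36,12.667239,,,
1,,,epidermis,1.123049478,4.4848
1,,,dermis,0.4877074867,76.8
2,,,epidermis,1.021532019,4.4848
2,,,dermis,0.4750089421,76.8
3,,,epidermis,1.214633767,4.4848
3,,,dermis,0.3565694677,76.8
4,,,epidermis,1.033956387,4.4848
4,,,dermis,0.4696133133,76.8
5,,,epidermis,1.256496609,4.4848
5,,,dermis,0.4299799265,76.8
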