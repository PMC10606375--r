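replicate,time_h,q_ug_per_cm2,layer,amount_ug,mass_mg
1,12,23.34035488,,,
1,14,31.86542778,,,
1,16,31.01438543,,,
1,18,41.20838944,,,
1,20,35.98689344,,,
1,22,51.84357763,,,
1,24,65.61867263,,,
1,36,105.7672004,,,
2,12,22.30066906,,,
2,14,29.88636303,,,
2,16,32.14644488,,,
2,18,42.45964983,,,
2,20,48.40344389,,,
2,22,77.55642821,,,
2,24,55.72627021,,,
2,36,77.57180225,,,
3,12,28.10436056,,,
3,14,32.15496665,,,
3,16,35.68911755,,,
3,18,47.55033363,,,
3,20,54.59096107,,,
3,22,54.88605252,,,
3,24,55.9262615,,,
3,36,71.05167906,,,
4,12,21.97516539,,,
4,14,35.30370536,,,
4,16,34.24708402,,,
4,18,50.42778433,,,
4,20,54.78717492,,,
4,22,53.85458333,,,
4,24,49.7696882,,,
4,36,98.25697972,,,
5,12,28.67229262,,,
5,14,33.72548187,,,
5,16,36.88311477,,,
5,18,38.44928444,,,
5,20,50.01138501,,,
5,22,63.80324606,,,
5,24,42.12664604,,,
5,36,92.06466829,,,
1,,,epidermis,6.947020274,4.4848
1,,,dermis,2.872260159,76.8
2,,,epidermis,6.756156085,4.4848
2,,,dermis,2.290804644,76.8
3,,,epidermis,6.828844601,4.4848
3,,,dermis,2.439923304,76.8
4,,,epidermis,7.777316948,4.4848
4,,,dermis,2.488137296,76.8
5,,,epidermis,5.708561702,4.4848
5,,,dermis,2.641898951,76.8
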