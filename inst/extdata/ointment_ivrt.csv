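replicate,time_h,q_ug_per_cm2,layer,amount_ug,mass_mg
1,0.5,0.5679377623,,,
1,1,1.230323377,,,
1,2,1.748037149,,,
1,4,5.487965752,,,
1,6,7.047296616,,,
1,8,8.967582282,,,
1,24,18.38707534,,,
2,0.5,0.5741702034,,,
2,1,1.187918956,,,
2,2,2.8412928,,,
2,4,5.064179275,,,
2,6,5.960199743,,,
2,8,6.827503825,,,
2,24,13.31122305,,,
3,0.5,0.5343765739,,,
3,1,1.052707076,,,
3,2,1.691356611,,,
3,4,5.303767194,,,
3,6,4.56107407,,,
3,8,8.115316941,,,
3,24,17.99752167,,,
4,0.5,0.5357767964,,,
4,1,0.8989210178,,,
4,2,1.847714934,,,
4,4,3.870891253,,,
4,6,5.698881845,,,
4,8,7.589839032,,,
4,24,16.50812437,,,
5,0.5,0.6506558758,,,
5,1,1.477518601,,,
5,2,2.621654925,,,
5,4,4.043768884,,,
5,6,4.972326059,,,
5,8,7.32548534,,,
5,24,19.23683066,,,
6,0.5,0.7581386945,,,
6,1,1.413989187,,,
6,2,2.026509778,,,
6,4,4.10234998,,,
6,6,9.322767969,,,
6,8,7.966895931,,,
6,24,16.20271315,,,
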