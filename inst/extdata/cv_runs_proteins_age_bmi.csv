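# Per-run performance indices reported for the 17-subject mucositis pilot
# cohort: twenty 10-fold cross-validations with 132 serum proteins plus
# age and BMI as predictors.
run,acc,sen,spc,ppv,npv
1,0.824,0.875,0.778,0.778,0.875
2,0.824,0.875,0.778,0.778,0.875
3,0.882,0.875,0.889,0.875,0.889
4,0.765,0.75,0.778,0.75,0.778
5,0.765,0.75,0.778,0.75,0.778
6,0.812,0.75,0.875,0.857,0.778
7,0.706,0.75,0.667,0.667,0.75
8,0.706,0.625,0.778,0.714,0.7
9,0.765,0.75,0.778,0.75,0.778
10,0.706,0.75,0.667,0.667,0.75
11,0.765,0.75,0.778,0.75,0.778
12,0.765,0.75,0.778,0.75,0.778
13,0.706,0.75,0.667,0.667,0.75
14,0.706,0.625,0.778,0.714,0.7
15,0.75,0.75,0.75,0.75,0.75
16,0.647,0.625,0.667,0.625,0.667
17,0.688,0.625,0.75,0.714,0.667
18,0.706,0.875,0.556,0.636,0.833
19,0.765,0.75,0.778,0.75,0.778
20,0.706,0.625,0.778,0.714,0.7
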