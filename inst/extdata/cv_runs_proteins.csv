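# Per-run performance indices reported for the 17-subject mucositis pilot
# cohort: twenty 10-fold cross-validations with 132 serum proteins as
# predictors. Used to demonstrate and check summarize_runs().
run,acc,sen,spc,ppv,npv
1,0.706,0.75,0.667,0.667,0.75
2,0.706,0.75,0.667,0.667,0.75
3,0.706,0.75,0.667,0.667,0.75
4,0.706,0.75,0.667,0.667,0.75
5,0.824,0.875,0.778,0.778,0.875
6,0.765,0.75,0.778,0.75,0.778
7,0.647,0.625,0.667,0.625,0.667
8,0.706,0.75,0.667,0.667,0.75
9,0.706,0.75,0.667,0.667,0.75
10,0.812,0.75,0.75,0.857,0.778
11,0.765,0.75,0.778,0.75,0.778
12,0.765,0.75,0.778,0.75,0.778
13,0.765,0.75,0.778,0.75,0.778
14,0.765,0.75,0.778,0.75,0.778
15,0.765,0.75,0.778,0.75,0.778
16,0.882,0.875,0.889,0.875,0.889
17,0.765,0.75,0.778,0.75,0.778
18,0.765,0.75,0.778,0.75,0.778
19,0.706,0.625,0.778,0.714,0.7
20,0.588,0.5,0.667,0.571,0.6
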