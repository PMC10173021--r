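variable,NHI_Q1,NHI_Q2,NHI_Q3,NHI_Q4,MA
n,40483,26955,21625,22201,10252
aged_65_plus,31254,17595,11895,13638,6734
female,15006,8988,6982,7866,5070
male,25477,17967,14643,14335,5182
diabetes,10346,6451,5046,5301,2756
hypertension,21185,12898,9781,10625,5307
metropolitan,17594,11385,9254,9525,4207
public_location,5734,4221,3781,3915,1087
witnessed,20090,13225,10392,10717,4378
bystander_cpr,24971,16487,13161,13397,5826
bystander_aed,1014,654,529,512,250
rti_lt8,23158,15247,12217,12867,5917
shockable,5690,4561,3771,3723,990
ed_level12,26384,17074,13765,14339,5939
cag,1872,1432,1211,1172,232
ttm,1173,817,721,670,161
surv_admission,7680,5546,4683,4711,1625
surv_discharge,2916,2250,1880,1832,465
good_neuro,1842,1458,1250,1108,216
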