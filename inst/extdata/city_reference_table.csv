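city,pm_mean,pm_sd,af_percent,af_low,af_high,attributable_deaths,ad_low,ad_high,ad_per_year,ady_low,ady_high
Ahmedabad,37.9,9.7,5.6,2.8,8.1,28680,13859,40632,2495,1230,3588
Bangalore,33.0,6.5,4.8,2.2,7.2,10509,5323,15652,2102,969,3167
Chennai,33.7,9.0,4.9,2.2,7.3,28674,12883,43266,2870,1329,4298
Delhi,113.0,64.5,11.5,5.2,16.4,95715,45449,135217,11964,5399,16983
Hyderabad,38.9,10.4,5.6,2.8,8.3,5552,2972,8274,1597,805,2363
Kolkata,55.2,35.3,7.3,4.0,10.5,45458,26227,63911,4678,2573,6735
Mumbai,41.7,18.5,5.6,3.0,8.0,30544,15507,43843,5091,2761,7340
Pune,45.3,22.6,5.9,3.3,8.6,7169,3866,10328,1367,761,1999
Shimla,28.4,6.9,3.7,1.9,5.6,281,132,415,59,30,90
Varanasi,82.1,35.3,10.2,6.2,14.4,8263,4973,11517,831,506,1178
Total,53.6,39.5,7.2,4.2,10.1,260845,151397,367490,33627,19443,47426
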