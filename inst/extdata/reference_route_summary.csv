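pig_type,route,pct_herds,pigs_at_risk,total_g,printed_mg_per_kg,printed_ddd_per_pig,printed_ddd_rate
sows,feed,24,781,9332,49.8,6.8,297.6
sows,injection,84,781,1895,10.1,1.4,61.1
sows,all_routes,92,781,11227,59.9,8.2,358.7
suckling,feed,60,9994,1516,37.9,5.8,252.3
suckling,injection,84,9994,843,21.1,5.1,220.6
suckling,all_routes,92,9994,2359,59.0,10.9,472.9
nursery,feed,76,13251,32525,213.4,24.1,463.4
nursery,injection,60,13251,275,1.8,0.2,4.1
nursery,water,40,13251,9354,61.4,3.6,69.2
nursery,all_routes,96,13251,42155,274.2,27.9,536.8
grower_finisher,feed,65,21638,161760,115.0,29.8,266.1
grower_finisher,injection,35,21638,487,0.3,0.04,0.4
grower_finisher,water,13,21638,20592,14.6,1.0,8.6
grower_finisher,all_routes,70,21638,182839,130.0,30.8,275.1
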