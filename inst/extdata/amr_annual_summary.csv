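point,year,method,mean_flow,n,natal_mean,natal_sd,pct_early,pct_early_legacy,fw_mean,fw_sd
delta-entry,2014,RST,981,100,45.0,12.4,73.0,85.0,NA,NA
delta-entry,2015,RST,1133,100,38.9,8.6,95.0,95.0,NA,NA
delta-entry,2016,KDT,4240,28,44.6,13.5,67.9,78.6,NA,NA
delta-entry,2017,KDT,15264,10,41.6,10.7,70.0,90.0,NA,NA
delta-entry,2018,KDT,3998,40,42.7,13.6,80.0,87.5,NA,NA
delta-seine,2014,seine,981,7,41.9,11.6,71.4,85.7,NA,NA
delta-seine,2015,seine,1133,5,50.4,13.2,40.0,80.0,NA,NA
delta-seine,2016,seine,4240,105,37.6,4.9,93.3,100.0,NA,NA
delta-seine,2017,seine,15264,38,36.4,2.4,97.4,100.0,NA,NA
delta-seine,2018,seine,3998,54,36.9,4.3,98.1,98.1,NA,NA
delta-exit,2014,MWT,981,5,56.0,12.9,20.0,60.0,73.2,2.2
delta-exit,2015,MWT,1133,6,63.5,16.3,16.7,33.3,73.3,17.5
delta-exit,2016,MWT,4240,26,53.9,18.0,46.2,57.7,81.3,7.9
delta-exit,2017,MWT,15264,15,66.4,11.2,6.7,13.3,84.5,6.4
delta-exit,2018,MWT,3998,9,55.3,18.6,44.4,44.4,78.9,5.6
delta-exit,2019,MWT,7977,50,62.3,15.7,22.0,26.0,79.4,13.2
adult,2011,carcass,8053,67,62.8,14.3,19.4,23.9,75.0,6.7
adult,2012,carcass,2276,319,75.7,14.1,6.6,9.7,81.8,8.9
adult,2013,carcass,1900,311,68.9,17.6,16.1,23.2,78.6,9.1
adult,2014,carcass,981,115,81.4,16.1,7.0,10.4,85.6,8.6
adult,2015,carcass,1133,89,79.4,12.2,3.4,10.1,81.9,8.5
adult,2016,carcass,4240,21,55.5,18.3,47.6,52.4,77.7,9.2
adult,2017,carcass,15264,58,70.5,10.9,1.7,13.8,76.5,9.3
adult,2018,carcass,3998,31,63.7,13.6,12.9,25.8,75.8,7.2
adult,2019,carcass,7977,42,62.5,17.0,23.8,33.3,76.9,9.1
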