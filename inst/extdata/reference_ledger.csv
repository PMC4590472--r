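variable,mean,b,a,pctVarTrend,T,A,theta,tMax,pctVarPeriodic,lag,phi,pctVarAr,pctVarTotal
temperature,15.7,,,,12,3.89,4.26,8.13,80.43,1,0.34,2.28,82.71
totalAbundance,5.83,,,,,,,,,1,0.20,4.32,4.32
lnaAbundance,5.47,0.016,-32.50,2.63,12,0.19,4.69,8.95,25.50,,,,28.13
hnaAbundance,5.55,,,,,,,,,,,,
totalSize,-1.27,-0.005,10.53,8.73,12,0.04,2.92,5.58,26.31,,,,35.04
lnaSize,-1.29,-0.004,7.25,4.19,12,0.04,2.44,4.67,31.84,,,,36.05
hnaSize,-1.24,-0.007,13.17,7.07,,,,,,,,,7.07
totalBiomass,1.02,,,,,,,,,1,0.21,4.77,4.77
lnaBiomass,0.65,,,,12,0.18,4.56,8.72,23.01,,,,23.01
pctLnaBiomass,44.2,0.59,-1179,2.58,12,8.40,5.00,9.54,31.32,,,,33.90
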