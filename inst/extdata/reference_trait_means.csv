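trait,unit,mean,min,max,h2
YLD,t/ha,8.5,6.6,9.8,0.69
GPC,%,11.9,10.5,13.7,0.81
SW,kg/hL,81.7,78.6,84.2,0.87
HD,days,132.6,125.3,145.7,0.97
HT,cm,93.4,72.0,116.0,0.95
SEEDA,mm2,16.0,12.6,18.4,0.94
SEEDL,mm,6.3,5.5,7.0,0.95
SEEDW,mm,3.5,3.2,3.7,0.87
TKW,g,41.1,30.8,47.1,0.84
GPY,t/ha,1.0,0.8,1.1,0.48
GPSM,grains/m2,20614.9,16514.2,24633.9,0.76
NMAX,-,0.9,0.8,0.9,0.68
GPA,-,834.8,727.8,899.0,0.88
FPA,-,339.7,257.4,467.3,0.87
SPA,-,287.7,230.2,342.2,0.35
DPA,-,627.4,530.7,732.0,0.83
TA,-,1314.7,1138.4,1443.8,0.75
TFN90,degC days,567.2,477.4,628.7,0.71
TFN50,degC days,688.5,592.2,742.5,0.82
TFN10,degC days,809.8,704.0,889.2,0.76
TFN1,degC days,942.2,820.3,1062.6,0.62
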