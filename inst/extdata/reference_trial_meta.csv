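location,latitude,longitude,plot_size,sowing_date,harvest_date,cycle_duration,mean_temp,sum_temp,n_frost_days,n_hot_days,cumulative_rainfall
Moinville-la-Jeulin,48.38,1.7,12.4,25/10/2019,11/07/2020,260,10.4,2709,35,13,347
Arvillers,49.73,2.65,10.6,29/10/2019,29/07/2020,274,10.4,2854,39,16,382
Pomacle,49.33,4.15,12.0,12/10/2019,19/07/2020,281,10.5,2953,47,21,430
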