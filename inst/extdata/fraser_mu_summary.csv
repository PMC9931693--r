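mu,n,lipid_mean,lipid_sd,lipid_min,lipid_max,ed_mean,ed_sd,ed_min,ed_max,fl_mean,fl_sd,fl_min,fl_max,wt_mean,wt_sd,wt_min,wt_max,run_first,run_50pct,run_last
Spring5_2,289,12.8,2.3,8.4,16.3,1900,194,1539,2200,660.9,67.4,507,752,7.0,2.4,2.7,11.3,2020-04-21,2020-07-13,2020-09-07
Spring4_2,9,12.2,1.7,10.7,16.3,1849,147,1720,2205,584.7,70.9,458,734,4.8,2.1,3.2,10.4,2020-04-22,2020-07-15,2020-08-02
Summer5_2,72,12.7,2.3,7.9,17.1,1890,196,1487,2271,658.3,55.0,484,751,7.1,1.9,2.7,11.8,2020-07-02,2020-08-13,2020-09-04
Summer4_1,966,10.8,1.8,3.4,19.8,1728,151,1101,2229,638.2,49.8,426,826,6.4,1.6,2.3,13.2,2020-07-16,2020-08-28,2020-09-29
Fall4_1,473,7.3,1.6,2.1,15.6,1436,138,985,2143,671.5,61.4,493,865,8.2,2.6,3.6,17.7,2020-08-24,2020-09-21,2020-10-27
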