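site,plot,proliferation,exclusion,fh_ph,mineral_ph,sand_pct,silt_pct,clay_pct
1,1-1,Yes,Yes,4.45,3.90,54.9,42.4,2.6
1,1-2,Yes,No,3.93,3.99,54.7,41.6,3.6
2,2-1,Yes,Yes,4.47,4.35,57.4,39.0,3.6
2,2-2,Yes,No,4.64,4.15,56.4,41.0,2.6
3,3-1,Yes,Yes,5.01,4.42,62.8,34.5,2.6
3,3-2,Yes,No,4.44,4.15,68.7,28.6,2.5
5,5-1,No,Yes,5.73,5.15,62.7,34.7,2.6
5,5-2,No,No,5.26,5.18,57.5,38.9,3.6
6,6-1,No,Yes,5.25,5.34,56.9,39.5,3.5
6,6-2,No,No,4.45,4.63,60.1,36.3,3.6
7,7-1,No,Yes,4.56,4.35,54.3,43.1,2.6
7,7-2,No,No,4.95,4.79,54.4,43.0,2.6
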