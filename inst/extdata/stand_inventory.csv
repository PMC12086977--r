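site,plot,proliferation,exclusion,total_canopy_ba_m2_ha,canopy_shade_rating,total_sapling_ba_m2_ha,beech_sapling_ba_m2_ha
1,1-1,Yes,Yes,35.29,1.44,3.28,3.11
1,1-2,Yes,No,35.73,2.55,3.04,2.25
2,2-1,Yes,Yes,29.18,1.17,3.23,2.50
2,2-2,Yes,No,40.96,1.94,2.67,2.38
3,3-1,Yes,Yes,25.02,1.65,3.10,3.10
3,3-2,Yes,No,31.00,1.90,2.49,2.36
5,5-1,No,Yes,34.64,2.19,0.93,0.0
5,5-2,No,No,41.04,1.56,0.88,0.0
6,6-1,No,Yes,30.25,1.00,0.37,0.0
6,6-2,No,No,32.50,1.01,0.71,0.0
7,7-1,No,Yes,36.23,1.34,0.82,0.0
7,7-2,No,No,31.54,1.53,0.06,0.02
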