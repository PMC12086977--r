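site,plot,proliferation,exclusion,mean_swc_pct,swc_cv_pct,instant_k_per_year
1,1-1,Yes,Yes,12.6,50.75,-0.467
1,1-2,Yes,No,22.81,22.87,-1.190
2,2-1,Yes,Yes,9.71,48.62,-0.206
2,2-2,Yes,No,14.20,22.55,-0.816
3,3-1,Yes,Yes,9.40,53.13,
3,3-2,Yes,No,11.26,29.29,-0.929
5,5-1,No,Yes,5.98,66.08,-0.204
5,5-2,No,No,12.87,24.34,-0.715
6,6-1,No,Yes,8.43,46.66,-0.260
6,6-2,No,No,18.59,26.24,-0.911
7,7-1,No,Yes,6.79,59.36,-0.424
7,7-2,No,No,13.71,21.10,-0.733
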