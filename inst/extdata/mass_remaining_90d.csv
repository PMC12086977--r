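proliferation,exclusion,species,mean_remaining,se,ll_95,ul_95,mass_loss_pct,component_mass_loss_pct,k_large,k_medium,k_small
Yes,Yes,maple,0.929,0.019,0.892,0.965,7.1,9.2,-0.264,-0.315,-0.356
Yes,Yes,beech,0.924,0.019,0.887,0.961,7.6,7.3,-0.315,-0.365,-0.315
Yes,Yes,mixed,0.915,0.019,0.899,0.972,8.5,8.3,-0.852,-0.416,-0.203
Yes,No,maple,0.756,0.015,0.743,0.803,24.4,22.9,-1.137,-1.309,-1.045
Yes,No,beech,0.809,0.015,0.766,0.826,19.1,20.9,-1.501,-0.913,-0.903
Yes,No,mixed,0.792,0.015,0.766,0.826,20.8,21.9,-0.690,-1.248,-0.994
No,Yes,maple,0.930,0.015,0.900,0.960,7.0,8.8,-0.311,-0.298,-0.291
No,Yes,beech,0.927,0.015,0.897,0.957,7.2,4.9,-0.315,-0.365,-0.284
No,Yes,mixed,0.935,0.015,0.908,0.967,6.5,6.9,-0.298,-0.237,-0.298
No,No,maple,0.824,0.015,0.794,0.854,17.6,22.4,-0.987,-0.737,-0.717
No,No,beech,0.845,0.015,0.815,0.875,15.5,16.3,-0.757,-0.609,-0.690
No,No,mixed,0.814,0.015,0.784,0.844,18.6,19.4,-0.724,-0.839,-1.014
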