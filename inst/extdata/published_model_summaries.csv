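trait,instrument,n,r2_main_pct,r2_interaction_pct,r2_full_pct,delta_f,model_f,df1,df2
neuroticism,NEO-PI-R,27,13.14,15.90,29.04,5.15,3.14,3,23
neuroticism,OPQ,32,24.20,21.41,45.61,11.02,7.83,3,28
neuroticism,BFI,38,1.14,7.83,8.97,2.92,1.12,3,34
extraversion,NEO-PI-R,27,52.67,3.44,56.11,1.80,9.80,3,23
extraversion,OPQ,32,19.62,25.94,45.56,13.35,7.81,3,28
extraversion,BFI,38,5.83,20.04,25.87,9.19,3.96,3,34
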