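item,mj_per_unit,unit,class
human_labour,1.96,h,labour
diesel,56.31,L,fuel
electricity,3.6,kWh,electricity
maize_seed,14.7,kg,seed
fertilizer_n,60.6,kg,fertilizer
fertilizer_p2o5,11.1,kg,fertilizer
fertilizer_k2o,6.7,kg,fertilizer
machinery,62.7,h,machinery
herbicide,238,kg,chemical
insecticide,199,kg,chemical
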