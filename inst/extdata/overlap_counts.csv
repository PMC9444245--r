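animal,nac_incl_double,vta_incl_double,total_reported,double
A01,269,111,380,0
A02,2995,544,3374,55
A03,2621,840,3251,70
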