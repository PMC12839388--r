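amplitude,x_nm,y_nm,loc_error_nm
1250.5,1000.25,2000.75,17
980.1,1013,1995.5,17
1500,985.625,2011.125,15
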