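study,year,axis,sedentary_upper_cpm,moderate_lower_cpm,moderate_upper_cpm,vigorous_lower_cpm,mvpa_lower_cpm,note
Puyau,2002,vertical,799,3200,8199,8200,3200,
Treuth,2004,vertical,100,3000,5200,5201,3000,
Freedson,2005,vertical,500,501,4000,4001,501,sedentary bound includes light intensity; vigorous range 4001-7600
Mattocks,2007,vertical,100,3581,6129,6130,3581,
Evenson,2008,vertical,100,2296,4011,4012,2296,
Pulsford,2011,vertical,99,2241,3840,3841,2241,
Vanhelst,2011,vertical,400,1901,3918,3919,1901,
Mackintosh,2012,vertical,372,2161,4806,4807,2161,
Jimmy,2013,vertical,NA,1596,2315,2316,1596,
Romanzini,2014,vertical,184,2428,3271,3272,2428,
Santos-Lozano,2013,vm,2114,2114,6547,6548,2114,sedentary bound includes light intensity; vigorous range 6548-11490
Hanggi,2013,vm,180,NA,NA,NA,3361,reports MVPA only (cpm above 3360)
Jimmy,2013,vm,NA,2952,3791,3792,2952,
Romanzini,2014,vm,720,3028,4447,4448,3028,
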