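variable,level,count_no,count_yes
sex,male,1988,4972
sex,female,3280,6170
education,incomplete_primary,365,1282
education,incomplete_secondary,1656,4250
education,complete_secondary,2165,3847
education,university,1082,1763
pa_level,low,2125,5549
pa_level,moderate,1985,3855
pa_level,high,1158,1738
fv_adequate,no,4812,10168
fv_adequate,yes,299,676
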