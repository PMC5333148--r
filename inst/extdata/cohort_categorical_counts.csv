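variable,count_control,count_ma,count_map,n_control,n_ma,n_map,reported_statistic,reported_p
gender_male,14,10,9,16,14,12,1.242,0.537
nicotine,7,9,12,16,14,12,9.583,0.008
cannabis,5,2,1,16,14,12,2.581,0.275
alcohol,6,7,1,16,14,12,5.125,0.077
mandrax,0,0,1,16,14,12,2.500,0.287
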