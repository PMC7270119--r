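cross_id,trait_name,unit,maternal_mean,paternal_mean,hybrid_mean
A,plant height,cm,37.2,34.7,47.1
B,plant height,cm,39.5,30.6,51.8
A,leaf length,cm,12.3,15.5,14.5
B,leaf length,cm,13.0,12.2,18.5
A,days to flowering,days,193,188,184
B,days to flowering,days,194,189,183
A,number of flowers,count,4.9,5.7,10.3
B,number of flowers,count,3.7,3.8,7.5
A,flower diameter,cm,14.4,14.0,13.3
B,flower diameter,cm,13.7,14.3,13.8
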