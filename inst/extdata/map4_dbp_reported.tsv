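variant	maf	averaged_mpp	empirical_mpp
3_47956424	0.343541	0.6081	0.0136
3_48040283	0.028049	0.6059	0.0115
3_47908815	0.002573	0.5052	0.0049
3_47912308	0.000515	0.3059	0.0152
3_47912736	0.000257	0.1105	0.0099
3_47912407	0.000257	0.1083	0.0083
3_47957996	0.022903	0.1065	0.0065
3_48040284	0.006948	0.1051	0.0083
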