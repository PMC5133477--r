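variant	maf	averaged_mpp	empirical_mpp
3_48040283	0.028049	0.6059	0.0140
3_47956424	0.343541	0.4082	0.0121
3_47957996	0.022903	0.4065	0.0050
3_47908815	0.000257	0.2553	0.0159
3_47912407	0.002573	0.2083	0.0100
3_47913606	0.000257	0.1485	0.0585
3_48016938	0.000257	0.1310	0.0410
3_47912736	0.000540	0.1106	0.0103
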