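day	total_clusters	abundant_clusters	total_estimate	abundant_estimate
0	12152	1919	132841	10426
7	13186	367	108253	1168
14	16907	1137	162868	5368
21	17930	861	158311	3013
28	15463	775	150605	3245
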