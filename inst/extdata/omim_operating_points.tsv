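h	tp	tpr	fpr	tpr_fpr
1	28	0.081	0.009	9
10	120	0.345	0.098	3.520
15	163	0.468	0.147	3.184
24	208	0.600	0.236	2.542
30	233	0.670	0.296	2.264
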