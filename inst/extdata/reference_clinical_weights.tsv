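problem	region	weight_abs
case	STAI-T	0.7977
case	PSWQ	0.4366
case	BDI	0.3902
case	IUS-12	0.1442
disorder	IUS-12	0.9331
disorder	BDI	0.2629
disorder	PSWQ	0.1934
disorder	STAI-T	0.1508
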