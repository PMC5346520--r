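problem	modality	sensitivity	specificity
case	clinical	96.97	95.83
case	cortisol	59.38	16.67
case	gm	75.76	41.67
case	wm	69.70	16.67
case	wave	84.38	95.83
disorder	clinical	63.16	50.00
disorder	cortisol	77.78	71.43
disorder	gm	78.95	57.14
disorder	wm	73.68	42.86
disorder	wave	77.78	57.14
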