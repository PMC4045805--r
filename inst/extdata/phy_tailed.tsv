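id	sequence	reads	position
1326087	ttggactgaagggagctccTT	112	B1
2403353	cttggactgaagggagctccT	95	B1
6094764	cttggactgaagggagctccTT	80	B1
2661774	ttggactgaagggagctccctT	73	B1
4673852	cttggactgaagggagctcccC	54	B1
3325799	ttggactgaagggagctcccC	40	B1
1418357	ttggactgaagggagctccT	36	B1
4245887	cttggactgaagggagctccctT	11	B1
1975016	attcaacgatgcatgagctgG	12	B1*
4917471	attcaacgatgcatgagctgC	6	B1*
2934896	attcaacgatgcatgagctgtT	5	B1*
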