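id	sequence	reads	position
4529255	tgttggtacatcatgagtcgT	28	B1
127628	tgttggtacatcatgagtcgcA	23	B1
5944084	tgttggtacatcatgagtcgcC	18	B1
4124961	tgttggtacatcatgagtcgctctT	10	B1
4831892	tgttggtacatcatgagtcgctT	10	B1
1311807	tgttggtacatcatgagtcT	9	B1
2744001	tgttggtacatcatgagtcgctctA	8	B1
4085913	tgttggtacatcatgagtcgTTC	5	B1
5323907	tgttggtacatcatgagtcgcCT	5	B1
5665375	aactcatgatgaaccaacttcT	41	B1*
1874545	ctcatgatgaaccaacttcacT	27	B1*
927297	tcatgatgaaccaacttcacT	46	B1*
4528246	catgatgaaccaacttcT	28	B1*
4270474	aatgaatgatgcggtagacaaaA	103	B2
4389442	aatgaatgatgcggtagacaaatC	48	B2
5577805	aatgaatgatgcggtagacaaatG	47	B2
1049979	aatgaatgatgcggtagacaaaC	32	B2
5744117	aatgaatgatgcggtagacaaatA	22	B2
3006666	aatgaatgatgcggtagacaaT	12	B2
5142252	aatgaatgatgcggtagacT	10	B2
5674106	aatgaatgatgcggtagacaaTT	9	B2
6175468	aatgaatgatgcggtagacaaaG	9	B2
4479594	aatgaatgatgcggtagacaT	7	B2
1992832	aatgaatgatgcggtagacaaG	6	B2
3318766	aatgaatgatgcggtagacaaaAC	6	B2
3095025	ttggatcattgattctctttgatgttggtacT	7	B3+
1404229	ttggatcattgattctctttgatgttggtacC	5	B3+
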