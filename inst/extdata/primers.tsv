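name	sequence	comment
amiRchs1-I	gatgttggtacatcatgagtcgctctctcttttgtattcc	amiRchs1 precursor synthesis
amiRchs1-II	gagcgactcatgatgtaccaacatcaaagagaatcaatga	amiRchs1 precursor synthesis
amiRchs1-III	gagcaactcatgatgaaccaacttcacaggtcgtgatatg	amiRchs1 precursor synthesis
amiRchs1-IV	gaagttggttcatcatgagttgctctacatatatattcct	amiRchs1 precursor synthesis
primer-A	ctgcaaggcgattaagttgggtaac	general amiRNA precursor synthesis primer
primer-B	gcggataacaatttcacacaggaaacag	general amiRNA precursor synthesis primer
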