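atc_code	ddd_value	ddd_unit
N05BA01	10	mg
N05BA02	30	mg
N05BA04	50	mg
N05CD02	5	mg
N05CD07	20	mg
N03AE01	8	mg
N05CF01	7.5	mg
N05CF02	10	mg
N05AA01	300	mg
N05AD01	8	mg
N05AH03	10	mg
N05AH04	400	mg
N05AX08	5	mg
N05AB03	30	mg
N05AN01	750	mg
N05AB04	100	mg
N06CA01	75	mg
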