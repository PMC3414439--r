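pair	cell_line	drug	level	dri
alsterpaullone+scriptaid	A549	alsterpaullone	0.25	2.013
alsterpaullone+scriptaid	A549	alsterpaullone	0.50	3.162
alsterpaullone+scriptaid	A549	alsterpaullone	0.75	4.968
alsterpaullone+scriptaid	A549	scriptaid	0.25	2.565
alsterpaullone+scriptaid	A549	scriptaid	0.50	3.020
alsterpaullone+scriptaid	A549	scriptaid	0.75	3.554
irinotecan+semustine	A549	irinotecan	0.25	1.452
irinotecan+semustine	A549	irinotecan	0.50	1.705
irinotecan+semustine	A549	irinotecan	0.75	2.002
irinotecan+semustine	A549	semustine	0.25	7.841
irinotecan+semustine	A549	semustine	0.50	7.589
irinotecan+semustine	A549	semustine	0.75	7.345
halofantrine+vinblastine	MDA-MB-231	halofantrine	0.50	14.17
halofantrine+vinblastine	MDA-MB-231	vinblastine	0.50	22.09
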