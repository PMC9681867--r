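stage	class	count
total	Genic region	129108
total	CDS-synonymous	40202
total	CDS-non-synonymous	30186
total	splice	51166
total	intron	7554
total	Intergenic region	140279
total	intergenic	50770
total	upstream	36605
total	downstream	33692
total	up/downstream	19212
filtered	Genic region	1313
filtered	CDS-synonymous	707
filtered	CDS-non-synonymous	489
filtered	splice	3
filtered	intron	114
filtered	Intergenic region	1628
filtered	intergenic	520
filtered	upstream	450
filtered	downstream	422
filtered	up/downstream	236
candidate	Genic region	328
candidate	CDS-synonymous	210
candidate	CDS-non-synonymous	118
candidate	splice	0
candidate	intron	0
candidate	Intergenic region	20
candidate	intergenic	1
candidate	upstream	8
candidate	downstream	8
candidate	up/downstream	3
core	Genic region	84
core	CDS-synonymous	48
core	CDS-non-synonymous	36
core	splice	0
core	intron	0
core	Intergenic region	3
core	intergenic	0
core	upstream	1
core	downstream	1
core	up/downstream	1
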