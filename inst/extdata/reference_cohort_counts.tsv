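characteristic	category	n
sex	male	17
sex	female	41
sex	unknown	16
age	<20	11
age	20~29	0
age	30~39	1
age	40~49	3
age	50~59	6
age	60~69	9
age	70~79	11
age	>80	3
age	unknown	30
reporter	consumer	50
reporter	physician	7
reporter	pharmacist	7
reporter	other	2
reporter	unknown	8
country	united states	50
country	other	24
outcome	hospitalization	16
outcome	life_threatening	3
outcome	disability	2
outcome	death	1
outcome	other_serious	24
route	oral	38
route	other	36
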