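sample_id	sex	birth_year	origin	camp	dam_id
E1	F	1974	captive	Kawlin	
E2	M	1968	wild	East Katha	
E3	F	1990	captive	Kawlin	E1
E4	unknown		unknown	West Katha	
E5	M	2001	captive	Kawlin	E3
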