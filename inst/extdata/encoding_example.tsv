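factor	category	or_value	is_reference
density	0-10%	1	TRUE
density	11-25%	1.28402541668774	FALSE
density	26-50%	1.64872127070013	FALSE
density	51-75%	2.11700001661267	FALSE
density	>75%	2.71828182845905	FALSE
first_delivery	<20	1	TRUE
first_delivery	20-24	1.07250818125422	FALSE
first_delivery	25-29	1.15027379885723	FALSE
first_delivery	30-34	1.23367805995674	FALSE
first_delivery	>34	1.32312981233744	FALSE
first_delivery	Nulliparous	1.16183424272828	FALSE
menopause	<46	1	TRUE
menopause	46-50	1.10517091807565	FALSE
menopause	>50	1.22140275816017	FALSE
menopause	Premenopause	1.82211880039051	FALSE
menopause	Menstruating	1.49182469764127	FALSE
menarche	>=15	1	TRUE
menarche	14	1.05127109637602	FALSE
menarche	13	1.10517091807565	FALSE
menarche	12	1.16183424272828	FALSE
menarche	<12	1.22140275816017	FALSE
menarche	Null	1	FALSE
family	none	1	TRUE
family	first>=50	1.41906754859326	FALSE
family	first<50	1.82211880039051	FALSE
family	second	1.22140275816017	FALSE
family	two_first	2.22554092849247	FALSE
family	two_second	1.49182469764127	FALSE
family	three_plus	2.71828182845905	FALSE
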