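name	tokens	cterm	note
NOSO-95C	Lys Dab(bOH) Dab(bOH) Gly Orn Pro His Lys Dha Lys	dbt-amide	canonical odilorhabdin, MW 1264
NOSO-95B	Lys Dab(bOH) Dab(bOH) Gly Orn Pro His Lys Dha HyLys	dbt-amide	one hydroxylysine (position 10 chosen; mass-equivalent to position 8)
NOSO-95A	Lys Dab(bOH) Dab(bOH) Gly Orn Pro His HyLys Dha HyLys	dbt-amide	hydroxylysines at positions 8 and 10
NOSO-95179	Lys Dab(bOH) Ala Gly Orn Pro His Lys Dha	free-acid	synthetic analog: Ala replaces Dab(bOH)3, Lys10-Dbt11 removed
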