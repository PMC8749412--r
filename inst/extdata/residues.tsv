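code	name	formula	amine_sites
Lys	L-Lysine	C6H12N2O	alpha,epsilon
HyLys	Hydroxylysine	C6H12N2O2	alpha,epsilon
Dab(bOH)	alpha,gamma-diamino-beta-hydroxybutyric acid	C4H8N2O2	alpha,gamma
Orn	D-Ornithine	C5H10N2O	alpha,delta
Dha	Z-alpha,beta-dehydroarginine	C6H10N4O	
Gly	Glycine	C2H3NO	alpha
Ala	L-Alanine	C3H5NO	alpha
Pro	L-Proline	C5H7NO	
His	L-Histidine	C6H7N3O	alpha
Arg	L-Arginine	C6H12N4O	alpha
Ser	L-Serine	C3H5NO2	alpha
Thr	L-Threonine	C4H7NO2	alpha
Val	L-Valine	C5H9NO	alpha
Leu	L-Leucine	C6H11NO	alpha
Ile	L-Isoleucine	C6H11NO	alpha
Phe	L-Phenylalanine	C9H9NO	alpha
Tyr	L-Tyrosine	C9H9NO2	alpha
Trp	L-Tryptophan	C11H10N2O	alpha
Met	L-Methionine	C5H9NOS	alpha
Cys	L-Cysteine	C3H5NOS	alpha
Asp	L-Aspartate	C4H5NO3	alpha
Glu	L-Glutamate	C5H7NO3	alpha
Asn	L-Asparagine	C4H6N2O2	alpha
Gln	L-Glutamine	C5H8N2O2	alpha
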