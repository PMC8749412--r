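# Published MS/MS ion list, monoacetylated NOSO-95C (precursor m/z 1307, 1+)
BEGIN IONS
TITLE=monoacetylated NOSO-95C fragmentation ion list
PEPMASS=1307
CHARGE=1+
654 1
1178 1
1020.6 1
904.6 1
688.4 1
733.5 1
517.3 1
635.9 1
1090.6 1
END IONS
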