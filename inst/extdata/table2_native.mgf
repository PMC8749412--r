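# Published MS/MS ion list, native NOSO-95C (precursor m/z 1265, 1+)
BEGIN IONS
TITLE=NOSO-95C native fragmentation ion list
PEPMASS=1265
CHARGE=1+
633 1
1136.7 1
1020.6 1
804.4 1
904.6 1
688.4 1
733.5 1
517.3 1
1048.6 1
END IONS
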