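# Published MS/MS ion list, biacetylated NOSO-95C (precursor m/z 1349, 1+)
BEGIN IONS
TITLE=biacetylated NOSO-95C fragmentation ion list
PEPMASS=1349
CHARGE=1+
675 1
1220.7 1
1062.6 1
846.4 1
904.6 1
688.4 1
733.5 1
517.3 1
1132.6 1
END IONS
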