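# Published MS/MS ion list, triacetylated NOSO-95C (precursor m/z 1391, 1+)
BEGIN IONS
TITLE=triacetylated NOSO-95C fragmentation ion list
PEPMASS=1391
CHARGE=1+
696 1
1262.7 1
1174.6 1
1104.6 1
946.6 1
775.5 1
687.4 1
517.3 1
1132.6 1
END IONS
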