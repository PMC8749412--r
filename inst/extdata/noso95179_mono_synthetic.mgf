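# SYNTHETIC stand-in peak list for monoacetylated NOSO-95179 (m/z 1064).
# The published figure for this analog reports the acetyl on Dab(bOH)2 but
# its raw ion list is not printed; these peaks are the computed one-decimal
# b/y ladder for that assignment (no raw data are reproduced here).
BEGIN IONS
TITLE=monoacetylated NOSO-95179, synthetic ladder (acetyl on Dab(bOH)2)
PEPMASS=1064
CHARGE=1+
532.3 1
935.5 1
891.5 1
777.4 1
763.4 1
706.4 1
649.4 1
535.3 1
END IONS
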