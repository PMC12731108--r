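# SYNTHETIC placeholder gene set for examples and tests only; not a
# clinical panel. Widely recognised colorectal cancer genes.
APC
MLH1
MSH2
MSH6
PMS2
MUTYH
POLE
POLD1
SMAD4
BMPR1A
STK11
PTEN
TP53
KRAS
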