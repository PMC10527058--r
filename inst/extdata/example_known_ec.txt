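# Illustrative knowledge list: gene symbols reported as expressed or
# modulated in endometrial cancer. Not a curated oncology resource; for
# examples and tests only.
WFDC2
ESR1
PGR
NCL
PRKCSH
CNR1
CNR2
GPR55
FAAH
NAPEPLD
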