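# Illustrative knowledge list: candidate gene symbols with at least one
# supporting publication on expression or function in other tissues.
GRN
APP
HEXA
CST3
CAD
QARS
SIAE
WARS
MYH8
CLTB
GOLIM4
SCARB2
BOD1L1
C14ORF142
C9ORF142
CCDC13
CNPY4
FAM169A
HN1L
PIGT
PLCL1
PMFBP1
SARS2
SCPEP1
SLC25A24
ZC3H4
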