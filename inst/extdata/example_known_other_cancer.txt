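# Illustrative knowledge list: gene symbols associated with cancers other
# than endometrial carcinoma (largely ribosomal proteins reported in
# breast, liver, gastric, colon and prostate tumours). For examples and
# tests only.
TP53
RPS3
RPS9
RPS14
RPS18
RPL8
RPL11
RPL18
RPL18A
RPL22
RPL24
RPL10A
RPL27A
RPLP1
RPLP2
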