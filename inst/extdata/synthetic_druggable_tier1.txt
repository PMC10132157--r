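# Synthetic stand-in for a druggable-genome tier-1 list (illustrative only;
# not the published resource). One symbol per line.
ERBB2
CDK6
FOLH1
EGFR
MET
ALK
BRAF
PIK3CA
AR
EZH2
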