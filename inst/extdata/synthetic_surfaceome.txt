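# Synthetic stand-in for a cell-surfaceome list (illustrative only; not the
# published resource). One symbol per line.
FOLH1
MUC1
CEACAM5
MSLN
ERBB2
EGFR
MET
TACSTD2
DLL3
STEAP1
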