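class,nottingham,edinburgh
Luminal A,288,225
Luminal N,205,152
Luminal B,186,140
Basal p53 altered,113,93
Basal p53 normal,96,70
HER2+/ER+,62,32
HER2+/ER-,85,55
Unclassified,38,51
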