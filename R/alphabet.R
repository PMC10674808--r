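# Shared alphabet constants (this file collates before every user).

RNA_BASES <- c("A", "C", "G", "U")
STOP_CODONS <- c("UAA", "UAG", "UGA")
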