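>chr1 test sequence
ACGTNNNNACGTACGTACGT
>chr2
NNACGTNNNN
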