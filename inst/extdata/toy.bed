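chr1	9990	10010	read1	0	+
chr1	0	100	read2	0	-
chr2	5	25	read3	0	+
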