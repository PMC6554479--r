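repeatA	chr1	98.5	100	1	0	1	100	501	600	1e-40	180
repeatA	chr1	97.0	100	3	0	1	100	500	401	1e-35	170
repeatB	chr2	95.0	50	2	0	1	50	41	90	1e-10	80
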