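protein	term	aspect
P00001	GO:0000002	MF
P00002	GO:0000002	MF
P00003	GO:0000002	MF
P00003	GO:0000003	MF
P00004	GO:0000002	MF
P00004	GO:0000003	MF
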