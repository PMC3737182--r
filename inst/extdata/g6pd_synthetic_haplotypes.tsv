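1	18334	36668	55001	73334	91667	110001	128334	146667	165001	183334	201667	220000	238334	256667	275000	293334	311667	330000	348334	366667	385000	403333	421667	440000
0	1	0	0	1	0	0	1	1	0	1	0	1	1	0	1	0	1	1	0	1	0	1	1	0
0	1	0	0	1	0	0	1	1	0	1	0	1	1	0	1	0	1	1	0	1	0	1	1	0
0	1	0	0	1	0	0	1	1	0	1	0	1	1	0	1	0	1	1	0	1	0	1	1	0
0	1	0	0	1	0	0	1	1	0	1	0	1	1	0	1	0	1	1	0	1	0	1	1	0
0	1	0	0	1	0	0	1	1	0	1	0	1	1	0	1	0	1	1	0	1	0	1	1	0
0	1	0	0	1	0	1	0	0	1	0	1	0	1	0	1	0	1	1	0	1	0	1	1	0
0	1	0	0	1	1	0	1	1	0	1	0	1	1	0	1	0	1	1	0	1	0	1	1	0
1	0	1	1	0	1	0	1	1	0	1	0	1	1	0	1	0	1	1	0	1	0	1	1	0
1	0	1	1	0	1	0	1	1	0	1	0	1	1	0	1	0	1	1	0	1	0	1	1	0
1	0	1	1	0	1	0	1	1	0	1	0	1	1	0	1	0	1	1	0	1	0	1	1	0
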