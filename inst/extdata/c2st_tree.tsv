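haplogroup	marker	parent
C2-M217	M217	ROOT
F3796	F3796	M217
F8951	F8951	M217
F3960	F11899	F3796
SK1072	F1072	F3796
F9747	F9747	F3796
F5481	F5481	F3796
SK1076	SK1076	F5481
F8949	F8949	F5481
F9033	F9033	F5481
F11165	F11165	F5481
Y12782	Y12782	F5481
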