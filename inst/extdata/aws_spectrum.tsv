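gene	mutation	count
awsO	A101C	1
awsO	A119C	1
awsR	A079C	9
awsR	C160T	1
awsR	C188T	1
awsR	C575T	2
awsR	A656C	1
awsX	C092T	1
awsX	∆100–138	2
awsX	T206G	1
awsX	∆229–261	20
awsX	T404G	1
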