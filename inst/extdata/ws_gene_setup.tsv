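gene	n_mutations
awsO	10
awsR	50
awsX	85
dgcH	50
mwsR	50
wspA	50
wspC	10
wspE	50
wspF	120
wspR	10
PFLU3448	2
PFLU3571	2
PFLU5960	2
PFLU0956 promoter	3
PFLU1349 promoter	3
PFLU5698 promoter	3
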