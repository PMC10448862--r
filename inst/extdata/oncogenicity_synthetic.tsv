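gene	alteration	oncogenicity
AR	T878A	Oncogenic
AR	H875Y	Oncogenic
AR	L702H	Oncogenic
AR	W742C	Likely Oncogenic
TP53	R175H	Oncogenic
TP53	R273H	Oncogenic
CTNNB1	S37F	Likely Oncogenic
PTEN	R130Q	Oncogenic
AR	E893K	Unknown
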