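pair	AU	UA	CG	GC	GU	UG
AU	-11	-11	-21.5	-21.5	-8	-8
UA	-11	-11	-21.5	-21.5	-8	-8
CG	-21.5	-21.5	-32	-32	-18.5	-18.5
GC	-21.5	-21.5	-32	-32	-18.5	-18.5
GU	-8	-8	-18.5	-18.5	-5	-5
UG	-8	-8	-18.5	-18.5	-5	-5
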