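p1	p2	dG
AU	AU	-0.93
UA	AU	-1.33
CG	AU	-2.11
GC	AU	-2.35
GU	AU	-1.3
UG	AU	-1.3
AU	UA	-1.1
UA	UA	-0.93
CG	UA	-2.08
GC	UA	-2.24
GU	UA	-1.3
UG	UA	-1.3
AU	CG	-2.24
UA	CG	-2.35
CG	CG	-3.26
GC	CG	-3.42
GU	CG	-1.3
UG	CG	-1.3
AU	GC	-2.08
UA	GC	-2.11
CG	GC	-2.36
GC	GC	-3.26
GU	GC	-1.3
UG	GC	-1.3
AU	GU	-1.3
UA	GU	-1.3
CG	GU	-1.3
GC	GU	-1.3
GU	GU	-0.5
UG	GU	-0.5
AU	UG	-1.3
UA	UG	-1.3
CG	UG	-1.3
GC	UG	-1.3
GU	UG	-0.5
UG	UG	-0.5
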