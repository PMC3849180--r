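# Nearest-neighbor RNA:RNA stacking free energies (kcal/mol, 37 C), Turner-2004-style.
# Doublet 5'-X1 X2-3' paired with 3'-Y1 Y2-5'; pair5 = X1Y1, pair3 = X2Y2.
# Table is reversal-symmetric: E(pair5,pair3) == E(rev(pair3), rev(pair5)).
# version: 1.0
pair5	pair3	energy
AU	AU	-0.93
AU	CG	-2.11
AU	GC	-2.08
AU	GU	-0.55
AU	UA	-1.10
AU	UG	-1.00
CG	AU	-2.24
CG	CG	-3.26
CG	GC	-2.36
CG	GU	-1.41
CG	UA	-2.08
CG	UG	-2.11
GC	AU	-2.35
GC	CG	-3.42
GC	GC	-3.26
GC	GU	-1.53
GC	UA	-2.11
GC	UG	-2.51
GU	AU	-1.27
GU	CG	-2.51
GU	GC	-2.11
GU	GU	-0.50
GU	UA	-1.00
GU	UG	 0.47
UA	AU	-1.33
UA	CG	-2.35
UA	GC	-2.24
UA	GU	-1.36
UA	UA	-0.93
UA	UG	-1.27
UG	AU	-1.36
UG	CG	-1.53
UG	GC	-1.41
UG	GU	 0.30
UG	UA	-0.55
UG	UG	-0.50
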