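# Loop initiation penalties (kcal/mol, 37 C): logarithmic Jacobson-Stockmayer form,
# monotone non-decreasing in size. bulge: total unpaired on one strand; internal: total on both.
# Internal-loop asymmetry: +0.6 kcal/mol per nt of |l1-l2|, capped at 3.0 (see meta.tsv).
# version: 1.0
type	size	energy
bulge	1	2.8
bulge	2	3.55
bulge	3	3.98
bulge	4	4.29
bulge	5	4.53
bulge	6	4.73
bulge	7	4.9
bulge	8	5.04
bulge	9	5.17
bulge	10	5.28
bulge	11	5.38
bulge	12	5.48
bulge	13	5.57
bulge	14	5.64
bulge	15	5.72
bulge	16	5.79
bulge	17	5.85
bulge	18	5.92
bulge	19	5.97
bulge	20	6.03
bulge	21	6.08
bulge	22	6.13
bulge	23	6.18
bulge	24	6.23
bulge	25	6.27
bulge	26	6.31
bulge	27	6.35
bulge	28	6.39
bulge	29	6.43
bulge	30	6.47
internal	2	2.25
internal	3	2.68
internal	4	2.99
internal	5	3.23
internal	6	3.43
internal	7	3.6
internal	8	3.74
internal	9	3.87
internal	10	3.98
internal	11	4.08
internal	12	4.18
internal	13	4.27
internal	14	4.34
internal	15	4.42
internal	16	4.49
internal	17	4.55
internal	18	4.62
internal	19	4.67
internal	20	4.73
internal	21	4.78
internal	22	4.83
internal	23	4.88
internal	24	4.93
internal	25	4.97
internal	26	5.01
internal	27	5.05
internal	28	5.09
internal	29	5.13
internal	30	5.17
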