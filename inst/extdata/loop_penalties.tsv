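# Simplified loop-destabilization penalties, 37 C, kcal/mol.
# Tabulated anchors follow Turner-family magnitudes; sizes beyond the
# anchors use Jacobson-Stockmayer extrapolation dG(n) = dG(n0) +
# 1.75*RT*ln(n/n0) with RT = 0.6163 kcal/mol. Values are monotone
# non-decreasing in loop size by construction.
# columns: loop_type  size(total unpaired nt)  dG
hairpin	3	5.40
hairpin	4	5.60
hairpin	5	5.70
hairpin	6	5.90
hairpin	7	6.00
hairpin	8	6.10
hairpin	9	6.20
hairpin	10	6.31
hairpin	11	6.42
hairpin	12	6.51
hairpin	13	6.60
hairpin	14	6.68
hairpin	15	6.75
hairpin	16	6.82
hairpin	17	6.89
hairpin	18	6.95
hairpin	19	7.01
hairpin	20	7.06
hairpin	21	7.11
hairpin	22	7.16
hairpin	23	7.21
hairpin	24	7.26
hairpin	25	7.30
hairpin	26	7.34
hairpin	27	7.38
hairpin	28	7.42
hairpin	29	7.46
hairpin	30	7.50
bulge	1	3.80
bulge	2	4.00
bulge	3	4.20
bulge	4	4.40
bulge	5	4.50
bulge	6	4.70
bulge	7	4.87
bulge	8	5.01
bulge	9	5.14
bulge	10	5.25
bulge	11	5.35
bulge	12	5.45
bulge	13	5.53
bulge	14	5.61
bulge	15	5.69
bulge	16	5.76
bulge	17	5.82
bulge	18	5.88
bulge	19	5.94
bulge	20	6.00
bulge	21	6.05
bulge	22	6.10
bulge	23	6.15
bulge	24	6.20
bulge	25	6.24
bulge	26	6.28
bulge	27	6.32
bulge	28	6.36
bulge	29	6.40
bulge	30	6.44
internal	2	3.10
internal	3	3.50
internal	4	3.80
internal	5	4.10
internal	6	4.30
internal	7	4.47
internal	8	4.61
internal	9	4.74
internal	10	4.85
internal	11	4.95
internal	12	5.05
internal	13	5.13
internal	14	5.21
internal	15	5.29
internal	16	5.36
internal	17	5.42
internal	18	5.48
internal	19	5.54
internal	20	5.60
internal	21	5.65
internal	22	5.70
internal	23	5.75
internal	24	5.80
internal	25	5.84
internal	26	5.88
internal	27	5.92
internal	28	5.96
internal	29	6.00
internal	30	6.04
# multiloop: linear model a + b*branches (unpaired bases free)
ml_init	.	3.40
ml_branch	.	0.40
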