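# Watson-Crick RNA-RNA nearest-neighbor stack free energies, 37 C, kcal/mol
# (Xia et al. 1998 delta-G37 values, as used by the Mfold family of tools).
# Key = top-strand dinucleotide 5'-XY-3'; the bottom strand is its exact
# Watson-Crick complement read 3'-X'Y'-5'. The table is closed under
# reverse complement: value(XY) == value(revcomp(XY)).
# init   = duplex initiation penalty
# term_au = per-terminal A.U (or U.A) closing-pair penalty
stack	AA	-0.93
stack	UU	-0.93
stack	AU	-1.10
stack	UA	-1.33
stack	CU	-2.08
stack	AG	-2.08
stack	CA	-2.11
stack	UG	-2.11
stack	GU	-2.24
stack	AC	-2.24
stack	GA	-2.35
stack	UC	-2.35
stack	CG	-2.36
stack	GG	-3.26
stack	CC	-3.26
stack	GC	-3.42
init	.	4.09
term_au	.	0.45
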