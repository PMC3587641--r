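# Conserved retroelement domain motifs. `x` = wildcard, x{n} repeats, [..] a
# residue class; DDE35 is the integrase catalytic triad with exactly 35
# residues between the second aspartate and the glutamate. `flavor` marks
# superfamily-diagnostic motifs (feeds the Gmr1-like evidence flag).
name	domain	flavor	pattern	max_mismatch
GAG_ZF	GAG	shared	Cx{2}Cx{4}Hx{4}C	0
PR_DxG	PR	shared	D[ST]G[ACS]	0
INT_ZF	INT	shared	Hx{4}Hx{30}Cx{2}C	0
INT_DDE	INT	shared	DDE35	0
RT_KARLVA	RT	copia	KARLVA	1
RT_YxDD	RT	shared	Y[VL]DD	0
RT_RMPFGL	RT	gypsy	RMPFGL	1
RH_TRPDI	RH	copia	TRPDI	1
RH_LTTDAS	RH	gypsy	LTTDAS	1
RH_ADALSR	RH	gypsy	ADALSR	1
RT_CORE_COPIA	RT	copia	WKQLTGMSPFLV	3
RT_CORE_GYPSY	RT	gypsy	FNSPLMTKWQVG	3
INT_CORE	INT	shared	GQKLAVRMTWPF	3
RH_CORE_COPIA	RH	copia	MSVPWFKQTLRG	3
RH_CORE_GYPSY	RH	gypsy	KPLWGQMVFTRS	3
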