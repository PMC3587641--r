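# RT/RH-region degenerate primers for Copia (CD) and Gypsy (GD) screens.
# direction: orientation relative to the element sense strand.
name	iupac	motif	direction
CD1	ARRGCNMGNYTNGTNGC	KARLVA	forward
CD2	ANNANRTCRTCNACRTA	YVDD	reverse
GD1	MGNMTGCCNTTYGGNYT	RMPFGL	forward
GD2	WSNGCRTCNGTNGSNA	LTTDAS	reverse
GD3	CKNGANASNSCRTCNGC	ADALSR	reverse
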