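# 3'-terminal sequences of tRNA acceptors used for PBS detection.
# tRNA-Met / tRNA-Trp 3' ends are the reverse complements of the
# canonical PBS sequences those tRNAs prime; the remaining 18
# acceptors are synthetic stand-ins (random 12-mers + CCA).
label	sequence	provenance
tRNA-Met	CCGGCTCTGCTACCA	complement_of_printed_PBS
tRNA-Trp	TACTTCAGGGTCACCA	complement_of_printed_PBS
tRNA-Ala	GATCGCGATCCACCA	synthetic_stand_in
tRNA-Arg	TACGACAAAACGCCA	synthetic_stand_in
tRNA-Asn	TATAGTTCATCGCCA	synthetic_stand_in
tRNA-Asp	AGAACAATCACACCA	synthetic_stand_in
tRNA-Cys	AAGCCGCGAGCCCCA	synthetic_stand_in
tRNA-Gln	AGTTTTCCCCATCCA	synthetic_stand_in
tRNA-Glu	GCTTAATTGCTTCCA	synthetic_stand_in
tRNA-Gly	AACTCCTGATCTCCA	synthetic_stand_in
tRNA-His	ATACCAGTTCGCCCA	synthetic_stand_in
tRNA-Ile	GAGAGCAGTACGCCA	synthetic_stand_in
tRNA-Leu	CTTACACTGGCTCCA	synthetic_stand_in
tRNA-Lys	TCCACCCTGTTGCCA	synthetic_stand_in
tRNA-Phe	ATTTAAAAAAAACCA	synthetic_stand_in
tRNA-Pro	TCACACTGTCCGCCA	synthetic_stand_in
tRNA-Ser	GTGATAACCTGGCCA	synthetic_stand_in
tRNA-Thr	CCGGATAGCCTCCCA	synthetic_stand_in
tRNA-Tyr	CCTCTTCAAAACCCA	synthetic_stand_in
tRNA-Val	CTGGTGACCCGCCCA	synthetic_stand_in
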