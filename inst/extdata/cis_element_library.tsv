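name	pattern
CAMTA-CGCG	MCGCGB
CAMTA-CGTG	MCGTGT
ABRE	ACGTG
G-box	CACGTG
ERE	ATTTCAAA
GT-1	GGTTAA
CGTCA-motif	CGTCA
TGACG-motif	TGACG
CAAT-box	CCAAT
TATA-box	TATAWAW
GATA-box	GATA
TCT-motif	TCTTAC
Box-4	ATTAAT
AuxRR-core	GGTCCAT
TGA-element	AACGAC
GARE-motif	TCTGTTG
P-box	CCTTTTG
TATC-box	TATCCCA
CAT-box	GCCACT
O2-site	GATGAYRTGR
GCN4-motif	TGAGTCA
MBS	CAACTG
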