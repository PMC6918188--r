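name	iupac	source
C-box	GACGTC	bZIP C-box
A-box	TACGTA	bZIP A-box
G-box	CACGTG	bZIP G-box
ABRE_M1	MNNACGTGKC	ABRE-core variant
ABRE_MEME	YKMCACGTGKC	ABRE-core variant
ABRE_M3	MCACGTGKC	ABRE-core variant
CBF3	YACGTGGC	ABRE-core variant
ABRE_M4	CACGTGGC	ABRE-core variant
OS_1K_001	CACGTGTC	predicted, 1-kb upstream
OS_1K_002	ACACGTGTC	predicted, 1-kb upstream
ABRE_7	ACGTGKC	ABRE core
ABRE_ACGTGTC	ACGTGTC	ABRE core
ABRE_ACGTGGC	ACGTGGC	ABRE core
ABREOSRAB21	ACGTSSSC	ABRE, rab21-type
ABRE_Arabidopsis	SRTACGTGTC	ABRE, dicot consensus
ABRE_Monocot	MGTACGTGKC	ABRE, monocot consensus
ABRE_Rice	CGTACGTGTC	ABRE, rice consensus
OS_1K_003	CGTACGYG	predicted, 1-kb upstream
ABA_responsive	AGTACGTGGC	ABA-responsive element
ABAVP1	TACGTGTC	ABA/VP1 response element
ABRE_TACGTGC	TACGTGC	ABRE core
GluB1	GTACGTG	glutelin promoter element
CE3	CACGCG	coupling element 3
CE_M3	CGCGTGKC	coupling-element variant
CE_M4	CGCGTCKC	coupling-element variant
CE_M5	CGCGTSKC	coupling-element variant
CE_M6	MCGCGTS	coupling-element variant
CE_M2	MCGCGTCD	coupling-element variant
CE_Arabidopsis	GACRCGTGKC	coupling element
CE	GMCGCGTGKC	coupling element
CE_Rice	GACGCGTGTC	coupling element, rice
Dreb1A	RCCGACNT	DREB1A binding site
DRE	RCCGAC	drought-responsive element
ERE	AGCCGCC	ethylene-responsive element
OS_1K_004	CGCCGCCG	predicted, 1-kb upstream
GCC_box	GCCGCC	ERF GCC-box
RAP2.6_GCCGCA	GCCGCA	ERF GCC variant
RAP2.3	GCCGAC	ERF GCC variant
RRTF1	GCCGTC	ERF GCC variant
RAP2.6_GCCGGC	GCCGGC	ERF GCC variant
GCCCA_M1	AGGCCCAA	GCC/CA variant
GCCCA_M2	CGGCCCAA	GCC/CA variant
GCCCA_M3	GGGCCCAA	GCC/CA variant
TCP_ClassII	GYGGNCCC	TCP class II site
SiteIIA_AGCCCA	AGCCCA	site IIa element
SiteIIA_GGCCCA	GGCCCA	site IIa element
SiteIIA_TGGGCC	TGGGCC	site IIa element
W-box	TTGACC	WRKY W-box
W-box_Y	TTGACY	WRKY W-box (degenerate)
GLK_motif	CCAATC	GLK recognition motif
WOX13	CAATCA	WOX13 site
WOX13_secondary	TAATTA	WOX13 secondary motif
OS_1D_002	TAATTAAT	predicted, 1-kb downstream
ICU4_ATHB51	AATWATT	HD-ZIP site
HDZIP	AATNATT	HD-ZIP binding site
Yabby_AATNATTA	AATNATTA	YABBY binding site
Yabby_AATNATAA	AATNATAA	YABBY binding site
OS_3K_004	GCTAGCTN	predicted, 3-kb upstream
OS_5U_002	AGCTAGCT	predicted, 5'-UTR
SHI_STY	CTAGCTAG	SHI/STY site
OS_UT_002	TAGCTAKN	predicted, intron
RY_motif	CATGCA	RY motif (B3 domain)
OS_1D_003	CATGCATG	predicted, 1-kb downstream
PBE-box	CACATG	PBE-box
DPBF_DCDC3	ACACATG	DPBF core
OS_5U_005	NMTCGATC	predicted, 5'-UTR
OS_1D_005	MTCGATCN	predicted, 1-kb downstream
OS_5U_004	NCGAWCGM	predicted, 5'-UTR
SPL_CGTAC	CGTAC	SPL binding site
SPL_CCGTAC	CCGTAC	SPL binding site
OS_1K_005	CAAAACGC	predicted, 1-kb upstream
ATCE	GACRCGTGKC	ABRE coupling element
CE_coexist	CGTGKCNS	co-existing coupling motif
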