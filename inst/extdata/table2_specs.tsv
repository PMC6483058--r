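# Curated onset (source) and apoptotic (sink) genes for ten KEGG disease
# pathways, as used for per-disease (source, sink) min-cut runs.
# Two gene tokens are ambiguous in the curation source and are kept as
# transcribed: CVID source "RAG" (possibly RAG2) and RCC sink "GFA"
# (possibly truncated).
disease_id	sources	sinks
AD	APP;CAPN1	CASP3;APBB1;MAPT
T2DM	INS;INSR	GLUT4
MEL	GF;NRAS;BRAF	CCND1;CDK4
PC	GF;PTEN;NKX3-1;CDKN1B	E2F1;TP53;BCL2;CASP9;BAD;FOXO1;MTOR
ALS	SOD1	MAP3K5;CASP3;NEFL;NEFM;NEFH
HD	Htt;GRM5	CASP3;ITPR1
PRION	PrPc	PKA
CVID	RAG1;RAG	ICOS
RCC	HGF;MET;EPAS1	SLC2A1;VEGFA;TGFB1;PDGFB;GFA
NAFLD	IL6;TNF;INS;LEP;ADIPOQ;FASLG	CASP3;CASP7;MAPK8
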