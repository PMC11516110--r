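# SYNTHETIC V-gene -> CDR1/CDR2 lookup (placeholder data).
# These loop sequences are deterministic stand-ins, NOT curated germline
# CDR1/CDR2 sequences; they exist so that gene-based resolution, the
# Table-4 fixture and the synthetic generator run end-to-end offline.
# Replace with an IMGT-derived table (same columns, one row per V gene,
# allele suffixes stripped) for biological use. Boundary convention of a
# replacement table should be documented by its provider; loop sequences
# here are 6-mers (CDR1) and 7-mers (CDR2).
gene	cdr1	cdr2
TRAV1-2	TSGFYG	NVLDGLH
TRAV3	VSGLRG	LYSAGEE
TRAV5	DSSSTY	IFSNMDM
TRAV12-1	NSAFQY	TYSSGNK
TRAV12-2	DRGSQS	IYSNGDK
TRAV13-1	DSASNY	IRSNVGE
TRAV14/DV4	STGYPT	ATKADDK
TRAV17	TSINNL	IRSNERE
TRAV26-2	TISGNE	GLKNNET
TRAV35	SIFNTW	LYKAGEL
TRBV2	SNHLYF	YYNCDPI
TRBV4-1	MGHDKM	SYDVKMK
TRBV5-1	SGHRSV	YFSETQR
TRBV6-1	MNHEYM	SVGAGIT
TRBV6-3	MNHEYS	SVGAGII
TRBV6-4	MRHNAL	SVGAGIA
TRBV6-5	MNHEYL	SVGAGIS
TRBV7-9	SGDLSV	YYNGEEK
TRBV9	SGDLSN	YYNGEES
TRBV11-2	SGHATL	FQNNGVV
TRBV12-4	SGHVSV	YFNNNVP
TRBV14	SGHDTV	YYEKEER
TRBV20-1	DFQATT	SNEGSKA
TRBV27	MNHNSM	SASEGTT
TRBV28	MDHENM	SYDVKMD
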