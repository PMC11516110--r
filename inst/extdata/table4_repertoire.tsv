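# Orphan/reference TCR pairs from the four deorphanization rounds, as
# printed (CDR3 and gene names verbatim; reported_distance/reported_ef are
# the published values, '' where not printed). role: orphan rows carry
# peptide 'orphan' or the printed reactivity annotation; reference rows the
# printed peptide. CDR1/2 are not printed and are resolved from V genes.
id	round	pair	role	patient	trav	traj	cdr3a	trbv	trbj	cdr3b	peptide	mhc	reported_distance	reported_ef
T4_01	1	r1p01	orphan	Mel#2	TRAV12-2	TRAJ52	CAVTTGGTSYGKLTF	TRBV11-2	TRBJ2-7	CASKGAPTIYYEQYF	orphan		0.13	1.4
T4_02	1	r1p01	reference	Mel#2	TRAV12-2	TRAJ52	CAVKGSGTSYGKLTF	TRBV9	TRBJ2-1	CASSLTGYEQFF	GLYDGMEHL
T4_03	1	r1p02	orphan	Mel#2	TRAV1-2	TRAJ26	CAVRFRDNYGQNFVF	TRBV5-1	TRBJ2-1	CASSLSWTSGNEQFF	orphan		0.09	2.3
T4_04	1	r1p02	reference	Mel#2	TRAV1-2	TRAJ28	CAVRTGYSGAGSYQLTF	TRBV5-1	TRBJ2-1	CASSYGNEQFFG	TADFDITEL
T4_05	1	r1p03	orphan	Mel#4	TRAV17	TRAJ12	CATVVRMDSSYKLIF	TRBV7-9	TRBJ2-1	CASSLIGVSSYNEQFF	orphan		0.11	4.5
T4_06	1	r1p03	reference	Mel#2	TRAV17	TRAJ12	CATVVRMDSSYKLIF	TRBV7-9	TRBJ2-1	CASSLVGEGWSDEQFF	TPRVTGGGAM
T4_07	1	r1p04	orphan	Mel#2	TRAV12-2	TRAJ49	CAGSTGNQFYF	TRBV27	TRBJ2-3	CASSPWGASDTQYF	orphan		0.10	1.6
T4_08	1	r1p04	reference	Mel#2	TRAV12-2	TRAJ49	CAVNAGNQFYF	TRBV4-1	TRBJ2-3	CASSPDRSADTQYF	ELAGIGILTV
T4_09	1	r1p05	orphan	Mel#2	TRAV12-1	TRAJ42	CVVNSYGGSQGNLIF	TRBV9	TRBJ1-2	CASSVVSGGTYGYTF	orphan		0.11	2.1
T4_10	1	r1p05	reference	Mel#2	TRAV12-2	TRAJ37	CAVKDGNTGKLIF	TRBV9	TRBJ1-2	CASSLTGYGYTF	GLYDGMEHL
T4_11	1	r1p06	orphan	Mel#4	TRAV14/DV4	TRAJ4	CVSGGYNKLIF	TRBV12-4	TRBJ1-6	CASGSGNSPLHF	orphan		0.11	4.5
T4_12	1	r1p06	reference	Mel#1	TRAV14/DV4	TRAJ4	CAMRAGGYNKLIF	TRBV14	TRBJ2-5	CASSHWTSGSGETQYF	ILRGSVAHK
T4_13	1	r1p07	orphan	Mel#1	TRAV13-1	TRAJ3	CAAGLGRYSSASKIIF	TRBV20-1	TRBJ2-5	CSAKRTSGHQETQYF	orphan		0.13	2.3
T4_14	1	r1p07	reference	Mel#1	TRAV13-1	TRAJ3	CAASDSSASKIIF	TRBV9	TRBJ2-5	CASSVGKETQYF	FAFGEPREL
T4_15	1	r1p08	orphan	Mel#1	TRAV26-2	TRAJ30	CILRDVGRDDKIIF	TRBV9	TRBJ2-5	CASSARQGRGETQYF	orphan		0.14	2.3
T4_16	1	r1p08	reference	Mel#1	TRAV13-1	TRAJ3	CAASDSSASKIIF	TRBV9	TRBJ2-5	CASSVGKETQYF	FAFGEPREL
T4_17	1	r1p09	orphan	Mel#1	TRAV35	TRAJ30	CAGQVVMDDKIIF	TRBV9	TRBJ2-5	CASSPPVGETQYF	orphan		0.14	2.3
T4_18	1	r1p09	reference	Mel#1	TRAV13-1	TRAJ3	CAASDSSASKIIF	TRBV9	TRBJ2-5	CASSVGKETQYF	FAFGEPREL
T4_19	1	r1p10	orphan	Mel#4	TRAV17	TRAJ12	CATVARMDSSYKLIF	TRBV7-9	TRBJ2-3	CASSLIGQGITDTQYF	orphan		0.14	4.5
T4_20	1	r1p10	reference	Mel#2	TRAV17	TRAJ12	CATVVRMDSSYKLIF	TRBV7-9	TRBJ2-1	CASSLVGEGWSDEQFF	TPRVTGGGAM
T4_21	1	r1p11	orphan	Mel#2	TRAV13-1	TRAJ4	CAVPGVLSGGYNKLIF	TRBV9	TRBJ1-1	CASSVASPNTEAFF	orphan		0.15	1.5
T4_22	1	r1p11	reference	Mel#2	TRAV13-1	TRAJ37	CASYSGNTGKLIF	TRBV9	TRBJ2-5	CASSVTSGTLYF	TADFDITEL
T4_23	2	r2p01	orphan	Mel#5	TRAV12-1	TRAJ12	CVVNGEDSSYKLIF	TRBV2	TRBJ2-2	CASSEGQVAPGELFF	EBV-reactive			7.6
T4_24	2	r2p01	orphan	Mel#5	TRAV12-1	TRAJ12	CVVNGMDSSYKLIF	TRBV2	TRBJ2-2	CASSAGQVAPGELFF	EBV-reactive		0.00
T4_25	2	r2p01	reference	10X	TRAV12-1	TRAJ12	CVVNGGDSSYKLIF	TRBV2	TRBJ2-2	CASSEGQVSPGELFF	GLCTLVAML	HLA-A*02:01	0.06
T4_26	2	r2p02	orphan	GI#1	TRAV5	TRAJ31	CAEDNNARLMF	TRBV20-1	TRBJ1-2	CSARDRTGNGYTF	orphan			28.0
T4_27	2	r2p02	reference	10X	TRAV5	TRAJ31	CAEDNNARLMF	TRBV20-1	TRBJ1-2	CSARDSTGNGYTF	GLCTLVAML	HLA-A*02:01	0.02
T4_28	3	r3p01	orphan	Lung#1	TRAV26-2	TRAJ53	CILSDGGSNYKLTF	TRBV2	TRBJ2-7	CASSEPGYEQYF	orphan		0.00
T4_29	3	r3p01	reference	Lung#1	TRAV26-2	TRAJ53	CILSDGGSNYKLTF	TRBV2	TRBJ2-7	CASSDPGYEQYF	DSNDYHILR	HLA-A*68:01
T4_30	3	r3p02	orphan	Lung#1	TRAV26-2	TRAJ53	CIPSDGGSNYKLTF	TRBV2	TRBJ2-1	CASSVPGYEQFF	orphan		0.00
T4_31	3	r3p02	reference	Lung#1	TRAV26-2	TRAJ53	CILSDGGSNYKLTF	TRBV2	TRBJ2-7	CASSDPGYEQYF	DSNDYHILR	HLA-A*68:01
T4_32	3	r3p03	orphan	Lung#1	TRAV3	TRAJ40	CAVRDISTTSGTYKYIF	TRBV28	TRBJ1-2	CASSPPGDPIYGYTF	orphan		0.06
T4_33	3	r3p03	reference	Lung#1	TRAV3	TRAJ40	CAVRDISTTSGTYKYIF	TRBV28	TRBJ1-6	CASSSPGDSYNSPLHF	DSNDYHILR	HLA-A*68:01
T4_34	4	r4p01	orphan	Mel#6	TRAV14/DV4	TRAJ26	CAMEEYGQNFVF	TRBV27	TRBJ2-4	CASSLSGGLYNEQFF	orphan		0.02
T4_35	4	r4p01	reference	Mel#6	TRAV14/DV4	TRAJ26	CAIINYGQNFVF	TRBV27	TRBJ2-4	CASSLSASGRVNIQYF	SLKLHYQL	HLA-B*08:01
T4_36	4	r4p02	orphan	Mel#6	TRAV12-2	TRAJ52	CALGSAGGTSYGKLTF	TRBV6-5	TRBJ1-2	CASSPSGAPANYGYTF	orphan		0.05
T4_37	4	r4p02	reference	10X	TRAV12-2	TRAJ52	CAVNLGLTAGGTSYGKLTF	TRBV6-4	TRBJ1-2	CASRAGTEISGYGYTF	ELAGIGILTV	HLA-A*02:01
T4_38	4	r4p03	orphan	Mel#6	TRAV12-2	TRAJ49	CAVNTGNQFYF	TRBV6-1	TRBJ1-5	CASSEAGVGQPQHF	orphan		0.06
T4_39	4	r4p03	reference	10X	TRAV12-2	TRAJ49	CAVPGSTGNQFYF	TRBV6-3	TRBJ1-5	CASSFGFGQPQHF	ELAGIGILTV	HLA-A*02:01
T4_40	4	r4p04	orphan	Mel#6	TRAV12-2	TRAJ47	CAVTLTKYGNKLVF	TRBV11-2	TRBJ1-2	CASSLGGGPIGYTF	orphan		0.06
T4_41	4	r4p04	reference	10X	TRAV12-2	TRAJ39	CAANAGNMLTF	TRBV11-2	TRBJ1-2	CASSLGGGTEAFF	ELAGIGILTV	HLA-A*02:01
T4_42	4	r4p05	orphan	Mel#6	TRAV12-2	TRAJ45	CAVNPGGGADGLTF	TRBV28	TRBJ2-1	CASTPPGTSGKSSYNEQFF	orphan		0.07
T4_43	4	r4p05	reference	10X	TRAV12-2	TRAJ32	CAVNGGGATNKLIF	TRBV28	TRBJ1-1	CAIPGPSNTEAFF	ELAGIGILTV	HLA-A*02:01
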