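gene_name	gene_id	chrom	start	end	strand	n_transcripts	aa_length	mw	pi	hydropathicity	membrane_type
TaWSD01-A	TraesCS1A02G385500	Chr1A	554830347	554835264	+	1	470	52.08	9.29	-0.13	Transmembrane
TaWSD01-B	TraesCS1B02G411900	Chr1B	637937998	637945870	+	1	535	58.27	9.31	-0.16	Transmembrane
TaWSD01-D	TraesCS1D02G393500	Chr1D	462991889	462997985	+	1	538	58.3	9.3	-0.13	Transmembrane
TaWSD02-B	TraesCS1B02G402900	Chr1B	632654884	632660030	-	2	509	56.14	7.79	0.04	Transmembrane
TaWSD03-D	TraesCS1D02G029300	Chr1D	11524330	11527811	+	1	510	56.38	9.36	-0.09	Transmembrane
TaWSD04-B	TraesCS2B02G007200	Chr2B	4502931	4515467	+	1	509	56.65	8.16	-0.1	Soluble
TaWSD04L-B	TraesCS2B02G019100	Chr2B	8766184	8773006	-	1	512	57.07	8.35	-0.08	Transmembrane
TaWSD04-D	TraesCS2D02G016300	Chr2D	7876792	7889878	+	1	515	57.54	8.74	-0.11	Soluble
TaWSD05-D	TraesCS2D02G002200	Chr2D	1912608	1922943	-	1	496	55.43	9.67	-0.03	Soluble
TaWSD06L-A	TraesCS3A02G013600	Chr3A	9810278	9814698	-	1	538	59.96	7.06	-0.02	Transmembrane
TaWSD06-A	TraesCS3A02G013700	Chr3A	9843405	9846523	-	3	496	55.19	9.07	0.02	Transmembrane
TaWSD06-B	TraesCS3B02G016400	Chr3B	6670118	6673010	-	3	500	55.68	9.07	0	Soluble
TaWSD06-D	TraesCS3D02G012000	Chr3D	4179986	4182963	-	3	497	55.48	9.16	-0.02	Transmembrane
TaWSD07-A	TraesCS3A02G017400	Chr3A	11023281	11028199	-	3	502	56.15	9.04	-0.01	Transmembrane
TaWSD07-B	TraesCS3B02G029900	Chr3B	13744964	13749320	+	1	504	56.45	8.87	0.02	Transmembrane
TaWSD08-A	TraesCS3A02G266700	Chr3A	491222820	491226810	+	1	518	57.76	7.75	-0.04	Transmembrane
TaWSD08-B	TraesCS3B02G300200	Chr3B	481649743	481652877	+	1	509	56.58	8.77	0.02	Transmembrane
TaWSD08-D	TraesCS3D02G266900	Chr3D	370123379	370126365	+	1	432	48.08	6.54	-0.01	Transmembrane
TaWSD09-A	TraesCS3A02G266800	Chr3A	491454647	491459021	+	2	516	57.08	8.43	-0.11	Transmembrane
TaWSD09-B	TraesCS3B02G300300	Chr3B	481909951	481914364	+	1	515	57.03	9.14	-0.13	Transmembrane
TaWSD09-D	TraesCS3D02G267000	Chr3D	370533318	370541637	+	2	514	56.76	7.4	-0.09	Transmembrane
TaWSD10-A	TraesCS3A02G297400	Chr3A	532315417	532320407	+	2	498	55.36	8.52	-0.03	Transmembrane
TaWSD10-B	TraesCS3B02G339300	Chr3B	545201896	545206411	-	3	498	55.22	8.98	-0.02	Transmembrane
TaWSD10-D	TraesCS3D02G304900	Chr3D	418782594	418787008	-	2	497	55.41	8.28	-0.02	Transmembrane
TaWSD11-B	TraesCS3B02G006700	Chr3B	3601450	3607208	+	3	501	55.62	9.1	0.04	Transmembrane
TaWSD11L-B	TraesCS3B02G011800	Chr3B	5230206	5234785	-	3	534	59.26	9.92	-0.07	Transmembrane
TaWSD12-A	TraesCS5A02G321800	Chr5A	534463680	534467925	+	1	529	58.5	7.83	-0.01	Transmembrane
TaWSD12-D	TraesCS5D02G328800	Chr5D	421159276	421163649	-	1	519	57.29	7.28	-0.01	Transmembrane
TaWSD12-Un	TraesCSU02G179300	ChrUn	270056904	270061362	-	1	519	57.29	7.28	-0.01	Transmembrane
TaWSD13-A	TraesCS5A02G321900	Chr5A	534569465	534573522	+	2	509	55.56	6.68	0.04	Transmembrane
TaWSD13-B	TraesCS5B02G322700	Chr5B	507370761	507374395	+	1	508	55.47	6.09	0.02	Transmembrane
TaWSD13-D	TraesCS5D02G328600	Chr5D	421084477	421090379	-	2	509	55.54	6.49	0.05	Transmembrane
TaWSD14-A	TraesCS5A02G322100	Chr5A	534625497	534629014	+	1	518	57.57	9.06	0.05	Transmembrane
TaWSD14L-B	TraesCS5B02G322300	Chr5B	507058471	507062451	+	2	516	56.9	6.96	0.08	Transmembrane
TaWSD14-B	TraesCS5B02G322800	Chr5B	507584712	507588567	+	3	513	56.76	9.1	0.01	Soluble
TaWSD14-D	TraesCS5D02G328500	Chr5D	420968589	420977820	-	1	516	56.88	8.48	-0.04	Soluble
TaWSD15-B	TraesCS5B02G322500	Chr5B	507187491	507192457	+	1	513	56.72	6.87	0.05	Transmembrane
TaWSD15-D	TraesCS5D02G328700	Chr5D	421133448	421138978	-	2	517	57.12	7.83	0.01	Transmembrane
TaWSD16-B	TraesCS5B02G495000	Chr5B	662851150	662856702	-	1	464	51.65	6.88	0.01	Transmembrane
TaWSD17-D	TraesCS6D02G014800	Chr6D	6156126	6159148	-	1	382	42.24	8.93	0.01	Transmembrane
TaWSD17-Un	TraesCSU02G029300	ChrUn	28199371	28204814	+	2	498	55.33	7.8	-0.03	Transmembrane
TaWSD18-D	TraesCS7D02G029000	Chr7D	14426236	14437067	+	1	499	55.77	8.19	-0.06	Transmembrane
TaWSD19-D	TraesCS7D02G111200	Chr7D	66953256	66958978	+	1	524	57.89	8.64	-0.03	Soluble
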