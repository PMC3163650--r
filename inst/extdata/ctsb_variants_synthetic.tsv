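type	genomic_position	hab_allele	lab_allele	location	utr	rel_position	mrna_position	snp_id
SNP	63251731	A	G	promoter	NA	-2269	NA	.
SNP	63251775	C	T	promoter	NA	-2225	NA	.
insertion	63251819	TGA		promoter	NA	-2181	NA	.
SNP	63251863	G	A	promoter	NA	-2137	NA	.
SNP	63251907	T	C	promoter	NA	-2093	NA	.
SNP	63251951	A	C	promoter	NA	-2049	NA	.
SNP	63252200	G	T	promoter	NA	-1800	NA	.
SNP	63252500	A	G	promoter	NA	-1500	NA	.
SNP	63252800	C	T	promoter	NA	-1200	NA	.
insertion	63253100	TGA		promoter	NA	-900	NA	.
SNP	63253400	G	A	promoter	NA	-600	NA	.
SNP	63253700	T	C	promoter	NA	-300	NA	.
SNP	63254099	A	C	exon-1	5'UTR	99	100	.
SNP	63254300	G	T	intron-1	NA	300	NA	.
deletion	63254500		CT	intron-1	NA	500	NA	.
SNP	63254700	A	G	intron-1	NA	700	NA	.
SNP	63254900	C	T	intron-1	NA	900	NA	.
SNP	63255080	G	A	intron-1	NA	1080	NA	.
SNP	63255129	A	G	exon-2	NA	1129	230	.
SNP	63255280	T	C	intron-2	NA	1280	NA	.
SNP	63255380	A	C	intron-2	NA	1380	NA	.
SNP	63255480	G	T	intron-2	NA	1480	NA	.
SNP	63255949	A	G	exon-3	NA	1949	350	.
SNP	63256100	A	G	intron-3	NA	2100	NA	.
SNP	63256132	C	T	intron-3	NA	2132	NA	.
SNP	63256165	G	A	intron-3	NA	2165	NA	.
SNP	63256197	T	C	intron-3	NA	2197	NA	.
insertion	63256229	CT		intron-3	NA	2229	NA	.
SNP	63256261	A	C	intron-3	NA	2261	NA	.
SNP	63256294	G	T	intron-3	NA	2294	NA	.
SNP	63256326	A	G	intron-3	NA	2326	NA	.
deletion	63256358		AG	intron-3	NA	2358	NA	.
SNP	63256391	C	T	intron-3	NA	2391	NA	.
SNP	63256423	G	A	intron-3	NA	2423	NA	.
insertion	63256455	AG		intron-3	NA	2455	NA	.
SNP	63256488	T	C	intron-3	NA	2488	NA	.
SNP	63256520	A	C	intron-3	NA	2520	NA	.
SNP	63256552	G	T	intron-3	NA	2552	NA	.
deletion	63256584		TGA	intron-3	NA	2584	NA	.
SNP	63256617	A	G	intron-3	NA	2617	NA	.
SNP	63256649	C	T	intron-3	NA	2649	NA	.
SNP	63257220	G	A	intron-4	NA	3220	NA	.
SNP	63257256	T	C	intron-4	NA	3256	NA	.
deletion	63257293		AG	intron-4	NA	3293	NA	.
SNP	63257329	A	C	intron-4	NA	3329	NA	.
SNP	63257365	G	T	intron-4	NA	3365	NA	.
insertion	63257401	AG		intron-4	NA	3401	NA	.
SNP	63257438	A	G	intron-4	NA	3438	NA	.
SNP	63257474	C	T	intron-4	NA	3474	NA	.
SNP	63257510	G	A	intron-4	NA	3510	NA	.
deletion	63257546		TGA	intron-4	NA	3546	NA	.
SNP	63257583	T	C	intron-4	NA	3583	NA	.
SNP	63257619	A	C	intron-4	NA	3619	NA	.
SNP	63257719	A	G	exon-5	NA	3719	620	.
SNP	63258250	A	G	intron-5	NA	4250	NA	.
insertion	63258450	TGA		intron-5	NA	4450	NA	.
SNP	63258650	C	T	intron-5	NA	4650	NA	.
SNP	63258850	G	A	intron-5	NA	4850	NA	.
SNP	63259050	T	C	intron-5	NA	5050	NA	.
SNP	63259250	A	C	intron-5	NA	5250	NA	.
SNP	63259450	G	T	intron-5	NA	5450	NA	.
SNP	63259650	A	G	intron-5	NA	5650	NA	.
SNP	63259920	C	T	intron-6	NA	5920	NA	.
deletion	63260070		AG	intron-6	NA	6070	NA	.
SNP	63260220	G	A	intron-6	NA	6220	NA	.
SNP	63260359	A	G	exon-7	NA	6359	860	.
SNP	63260530	T	C	intron-7	NA	6530	NA	.
SNP	63260680	A	C	intron-7	NA	6680	NA	.
SNP	63261060	G	T	intron-8	NA	7060	NA	.
SNP	63261260	A	G	intron-8	NA	7260	NA	.
insertion	63261460	AG		intron-8	NA	7460	NA	.
SNP	63261660	C	T	intron-8	NA	7660	NA	.
SNP	63261860	G	A	intron-8	NA	7860	NA	.
deletion	63262060		AG	intron-8	NA	8060	NA	.
SNP	63262199	A	G	exon-9	NA	8199	1100	.
SNP	63262974	A	G	exon-10	NA	8974	1175	.
SNP	63263199	G	T	exon-10	3'UTR	9199	1400	.
SNP	63263650	C	T	DER	NA	9650	NA	.
SNP	63264000	T	C	DER	NA	10000	NA	.
SNP	63264032	A	C	DER	NA	10032	NA	.
SNP	63264063	G	T	DER	NA	10063	NA	.
insertion	63264095	TGA		DER	NA	10095	NA	.
SNP	63264127	A	G	DER	NA	10127	NA	.
SNP	63264159	C	T	DER	NA	10159	NA	.
SNP	63264190	G	A	DER	NA	10190	NA	.
SNP	63264222	T	C	DER	NA	10222	NA	.
deletion	63264254		AG	DER	NA	10254	NA	.
SNP	63264286	A	C	DER	NA	10286	NA	.
SNP	63264317	G	T	DER	NA	10317	NA	.
SNP	63264349	A	G	DER	NA	10349	NA	.
SNP	63264800	G	A	DER	NA	10800	NA	.
deletion	63265200		AG	DER	NA	11200	NA	.
SNP	63265500	T	C	DER	NA	11500	NA	.
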