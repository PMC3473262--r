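id	species	length_aa	architecture	prior_names	anchor_name	active	activity_reason	not_family	group	proposed_name
At3g27925	At	439	PD-PDZ	DEG1,O22609	Deg1	1		0	Deg1	AtDeg1
At2g47940	At	607	PD-PDZ-PDZ	DEG2,O82261	Deg2	1		0	Deg2	AtDeg2
At1g65630	At	559	PD-PDZ-PDZ	DEG3,Q9SHZ1	Deg3	1		0	Deg3	AtDeg3
At1g65640	At	518	PD-PDZ-PDZ	DEG4,Q9SHZ0	Deg4	1		0	Deg4	AtDeg4
At4g18370	At	323	PD	DEG5,Q9SEL7	Deg5	1		0	Deg5	AtDeg5
At1g51150	At	219	PD_ia	DEG6,Q9C691	Deg6	0	TRUNCATED_PD	0	Deg6	AtDeg6
At3g03380	At	1097	PD-PDZ-PDZ-PD_ia-PDZ-PDZ	DEG7,Q8RY22	Deg7	1		0	Deg7	AtDeg7
At5g39830	At	448	PD-PDZ	DEG8,Q9LU10	Deg8	1		0	Deg8	AtDeg8
At5g40200	At	592	PD-PDZ-PDZ	DEG9,Q9FL12	Deg9	1		0	Deg9	AtDeg9
At5g36950	At	586	PD-PDZ-PDZ	DEG10,Q9FIV6	Deg10	1		0	Deg10	AtDeg10
At3g16540	At	555	PD-PDZ-PDZ	DEG11,Q9LK71	Deg11	1		0	Deg11	AtDeg11
At3g16550	At	499	PD-PDZ-PDZ	DEG12,Q9LK70	Deg12	1		0	Deg12	AtDeg12
At5g40560	At	486	PD-PDZ-PDZ	DEG13,Q9FM41	Deg13	1		0	Deg13	AtDeg13
At5g27660	At	429	PD-PDZ	DEG14,Q3E6S8	Deg14	1		0	Deg14	AtDeg14
At1g28320	At	709	NT-PD	DEG15,Q8VZD4	Deg15	1		0	Deg15	AtDeg15
At5g54745	At	198	PD_ia	DEG16,Q3E8B4	Deg16	0	MISSING_TRIAD_RESIDUE	0	Deg16	AtDeg16
POPTR_0001s34960	Pt	429	PD-PDZ	Pt706718,PtDeg1		1		0	Deg1	PtDeg1
POPTR_0014s12970	Pt	592	PD-PDZ-PDZ	Pt572750,PtDeg2.1		1		0	Deg2	PtDeg2.1
POPTR_0020s00220	Pt	624	PD-PDZ-PDZ	Pt775566,PtDeg2.2		1		0	Deg2	PtDeg2.2
POPTR_0011s02330	Pt	316	PD	Pt771291,PtDeg5.1		1		0	Deg5	PtDeg5
POPTR_0017s03050	Pt	1128	PD-PDZ-PDZ-PD_ia-PDZ-PDZ	Pt816849,PtDeg7.1		1		0	Deg7	PtDeg7.1
POPTR_0004s08740	Pt	1080	PD-PDZ-PDZ-PD_ia-PDZ-PDZ	Pt555951,PtDeg7.2		1		0	Deg7	PtDeg7.2
POPTR_0004s08720	Pt	1117	PD-PDZ-PDZ-PD_ia-PDZ-PDZ	Pt714140,PtDeg7.3		1		0	Deg7	PtDeg7.3
POPTR_0004s13440	Pt	465	PD-PDZ	Pt199267,PtDeg8		1		0	Deg8	PtDeg8
POPTR_0015s08440	Pt	556	PD-PDZ-PDZ	Pt251989,PtDeg9.1		1		0	Deg9	PtDeg9.1
POPTR_0012s07930	Pt	559	PD-PDZ-PDZ	Pt728836,Pt823359,PtDeg9.2		1		0	Deg9	PtDeg9.2
POPTR_0008s07940	Pt	587	PD-PDZ-PDZ	B9HI10		1		0	Deg10	PtDeg10
POPTR_0013s01900	Pt	422	PD-PDZ	Pt662713,Pt662714,PtDeg14.1,PtDeg14.2		1		0	Deg14	PtDeg14
POPTR_0004s04650	Pt	752	NT-PD	Pt555773,PtDeg15.1		1		0	Deg15	PtDeg15.1
POPTR_0011s05510	Pt	729	NT-PD	Pt266544,PtDeg15.2		1		0	Deg15	PtDeg15.2
POPTR_0018s04140	Pt	356	PD_ia-PDZ	Pt787034,PtDeg17.1		0	MISSING_TRIAD_RESIDUE	0	Deg17	PtDeg17.1
POPTR_0394s00220	Pt	298	PD_ia-PDZ	Pt586371,PtDeg17.2		0	MISSING_TRIAD_RESIDUE	0	Deg17	PtDeg17.2
POPTR_0018s04150	Pt	364	PD_ia-PDZ	Pt577788,PtDeg17.3		0	MISSING_TRIAD_RESIDUE	0	Deg17	PtDeg17.3
Os01g0278600	Os	470	PD_ia-PDZ	LOC_Os01g17070,OsDegP1		0	MISSING_TRIAD_RESIDUE	0		OsDeg-like 1
Os02g0712000	Os	1092	PD-PDZ-PDZ-PD_ia-PDZ-PDZ	LOC_Os02g48180,OsDegP2		1		0	Deg7	OsDeg7
Os02g0742500	Os	567	PD-PDZ-PDZ	LOC_Os02g50880,OsDegP3		1		0	Deg9	OsDeg9.1
LOC_Os03g62900	Os	299	PD	OsDegP4,Q84SQ1				1		OsDeg-like 6
Os04g0459900	Os	445	PD-PDZ	LOC_Os04g38640,OsDegP5		1		0	Deg8	OsDeg8
Os05g0147500	Os	596	PD-PDZ-PDZ	LOC_Os05g05480,OsDegP6		1		0	Deg2	OsDeg2
Os05g0417100	Os	614	PD-PDZ-PDZ	LOC_Os05g34460,OsDegP7		1		0	Deg10	OsDeg10
Os05g0497700	Os	722	NT-PD	LOC_Os05g41810,OsDegP8		1		0	Deg15	OsDeg15
Os05g0568900	Os	437	PD-PDZ	LOC_Os05g49380,OsDegP9		1		0	Deg1	OsDeg1
Os06g0234100	Os	628	PD-PDZ-PDZ	LOC_Os06g12780,OsDegP10		1		0	Deg9	OsDeg9.2
Os08g0144400	Os	496	NT-PD_ia-PDZ	LOC_Os08g04920,OsDegP11		0	MISSING_TRIAD_RESIDUE	0		OsDeg-like 2
Os11g0246600	Os	472	PD-PDZ	LOC_Os11g14170,OsDegP12		1		0	Deg14	OsDeg14
Os12g0141500	Os	228	PD	LOC_Os12g04740,OsDegP13				1		OsDeg-like 3
Os12g0141600	Os	593	PD_ia-PD_ia	LOC_Os12g04750,OsDegP14		0	MISSING_TRIAD_RESIDUE	0		OsDeg-like 4
Os12g0616600	Os	313	PD	LOC_Os12g42210,OsDegP15		1		0	Deg5	OsDeg5
Os03g0608600	Os	271	PD	LOC_Os03g41170				1		OsDeg-like 5
Pp1s160_79V6	Pp	500	PD-PDZ	A9T3R3		1		0	Deg1	PpDeg1.1
Pp1s198_100V6	Pp	475	PD-PDZ	A9TBD2		1		0	Deg1	PpDeg1.2
Pp1s79_92V6	Pp	501	PD-PDZ	A9SHE2		1		0	Deg1	PpDeg1.3
Pp1s21_138V6	Pp	486	PD-PDZ	A9RQ01		1		0	Deg1	PpDeg1.4
Pp1s8_140V6	Pp	618	PD-PDZ-PDZ	A9RGN6		1		0	Deg2	PpDeg2
Pp1s63_95V6	Pp	362	PD	A9SBN1		1		0	Deg5	PpDeg5
Pp1s237_5V6	Pp	1076	PD-PDZ-PDZ-PD_ia-PDZ-PDZ	A9TIB2		1		0	Deg7	PpDeg7.1
Pp1s21_327V6	Pp	1072	PD-PDZ-PDZ-PD_ia-PDZ-PDZ	A9RQ61		1		0	Deg7	PpDeg7.2
Pp1s31_50V6	Pp	493	PD-PDZ	A9RVV4		1		0	Deg8	PpDeg8
Pp1s176_87V6	Pp	612	PD-PDZ-PDZ	A9T734		1		0	Deg9	PpDeg9.1
Pp1s1_203V6	Pp	540	PD-PDZ	A9RB23		1		0	Deg9	PpDeg9.2
Pp1s55_7V5	Pp	651	PD-PDZ-PDZ			1		0	Deg10	PpDeg10
Pp1s180_15V6	Pp	473	PD-PDZ	A9T7W1		1		0	Deg14	PpDeg14
Pp1s196_28V6	Pp	784	NT-PD	A9TAV2		1		0	Deg15	PpDeg15
Pp1s152_166V5.1	Pp	339	PD-PDZ			1		0	Deg1-group-like	PpDeg1-group-like
Pp1s176_111V6	Pp	527	PD_ia-PDZ			0	MISSING_TRIAD_RESIDUE	0		
Pp1s67_44V6	Pp	408	PD_ia-PDZ	A9SD45		0	MISSING_TRIAD_RESIDUE	0		
Cre02.g088400	Cr	530	PD-PDZ	Deg1,Deg1A,A8I8X2		1		0	Deg1	CrDeg1.1
Cre14.g630550	Cr	555	PD-PDZ	Deg13		1		0	Deg1	CrDeg1.2
Cre12.g498500	Cr	462	PD-PDZ	Deg11		1		0	Deg1	CrDeg1.3
Cre02.g092000	Cr	656	PD-PDZ-PDZ	Deg2,A8I9B8		1		0	Deg2	CrDeg2
Cre02.g110600	Cr	356	PD	Deg5,A8I3D5		1		0	Deg5	CrDeg5
Cre03.g180650	Cr	1108	PD-PDZ-PDZ-PD_ia-PDZ-PDZ	Deg7,A8JH35		1		0	Deg7	CrDeg7
Cre01.g028350	Cr	436	PD-PDZ	Deg8,A8HQB3		1		0	Deg8	CrDeg8
Cre19.g752200	Cr	1353	PD-betaglycanhydrolase	A8JBP6		1		0	Deg9	CrDeg9.1
Cre14.g617600	Cr	619	PD-PDZ-PDZ	Deg9,A8HNV3		1		0	Deg9	CrDeg9.2
Cre01.g013300	Cr	739	PD-PDZ-PDZ	Deg10		1		0	Deg10	CrDeg10
Cre12.g548200	Cr	1249	NT-PD	A8IYE3		1		0	Deg15	CrDeg15
Cre07.g332050	Cr	284	PD	A8IGX3				1		
Cre13.g579900	Cr	415	PD_ia-PDZ-PDZ			0	MISSING_TRIAD_RESIDUE	0		
Cre03.g203730	Cr	789	PD_ia-PDZ	CrDegO,A8IXF5		0	MISSING_TRIAD_RESIDUE	0		
Cre38.g785300	Cr	319	PD_ia	A8JG98		0	MISSING_TRIAD_RESIDUE	0		
Syn_HtrA	Syn	0	PD-PDZ	P73354		1		0		
Syn_HhoA	Syn	0	PD-PDZ	P72780		1		0		
Syn_HhoB	Syn	0	PD-PDZ	P73940		1		0		
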