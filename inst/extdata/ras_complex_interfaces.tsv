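group	id	members	description	positions
RasGef	1LFD	1LFD	Interaction of Ras with RalGDS	G12,Y32,D33,P34,I36,E37,D38,S39,Y40,Q61,E62,E63,Y64,S65,A66,M67
RasGef	1NVU	1NVU;1NVX;1NVW;1NVV	Feedback activation by Ras-GTP of the Ras-specific nucleotide exchange factor SOS	S17,T20,I21,Q22,I24,N26,H27,D30,E31,Y32,D33,P34,I36,E37,D38,Y40,K42,Q43,V44,D54,I55,D57,A59,G60,Q61,E63,Y64,S65,A66,M67,D69,Q70,Y71,R73,R102,R149
RasGef	1XD2	1XD2	Autoinhibition in the Ras activator Son of sevenless: ternary Ras:SOS:Ras-GDP complex	Q22,I24,N26,H27,D33,P34,I36,E37,D38,K42,Q43,V44,L56,E63,Y64,A66,M67,Q70,Y71,R149
RasGef	1BKD	1BKD	Structural basis of the activation of Ras by Sos: H-Ras with SOS-1	S17,I21,Y32,P34,Y40,D54,I55,D57,A59,G60,Q61,E63,Y64,S65,A66,M67,D69,Q70,Y71,R73,R102
RapGef	3CF6	3CF6	Epac2 in complex with a cyclic AMP analogue and RAP1B	S17,T20,I21,H27,Y32,P34,E37,Y40,D54,I55,L56,D57,A59,G60,Q61,Y64,A66,M67,D69,Q70,Y71,Q99
RasGap	1WQ1	1WQ1	The Ras-RasGAP complex: structural basis for GTPase activation	A11,G12,G13,I21,Y32,D33,P34,I36,E37,D38,S39,Y40,G60,Q61,E62,E63,Y64,K88,D92
Antibody	2UZI	2UZI	Single antibody domain targeting the interaction of signal transduction proteins with RAS	I21,V29,D33,P34,I36,E37,D38,Y40,Q61,Y64
Antibody	2VH5	2VH5	HRAS(G12V) - anti-RAS FV (disulfide free mutant) complex	I21,V29,D33,P34,I36,E37,D38,Y40,D57,Q61,Y64
Antibody	3DDC	3DDC	Ras effector interaction between tumour suppressor NORE1A and Ras switch II	I24,Q25,I36,D38,Y40,Y64,M67
RBD	1HE8	1HE8	Ras binding to its effector phosphoinositide 3-kinase gamma	I21,D33,I36,E37,D38,S39,Y40
RBD	3KUC	3KUC;1GUA	Rap1A with RafRBD: Ras/Rap effector specificity by charge reversal	I21,D33,I36,E37,D38,S39,Y40,R41
RBD	3KUD	3KUD	Ras-GDP interactions with mutants of Raf	I21,E37,D38,S39,Y40,R41
RBD	1K8R	1K8R	Ras-Byr2RBD complex: structural basis for Ras effector recognition	I36,E37,D38,S39,Y40,R41,D54
RBD	1C1Y	1C1Y	c-Raf1 in complex with Rap1A and a GTP analogue	I21,I36,E37,D38,S39,Y40,R41
Other	1ZC3	1ZC3;1ZC4	Ral-binding domain of Exo84 in complex with the active RalA	D47,G48,E49,T50,C51,L52,M67,G75,F78,V81,F82
Other	2A9K	2A9K;2A78	C3bot-NAD-RalA complex: RalA and mono-ADP-ribosyltransferase C3	T20,I21,Q22,L23,D69,Y71,M72,G75,L79,A83,V103,S106,D107,P110
Other	2C5L	2C5L	PLC epsilon Ras association domain with HRas	I24,Q25,I36,D38,S39,Y40,D47,S127,Q131,A134,Y141,I142,E143,D154,R161,R164,Q165
Other	4DXA	4DXA	Rap1 in complex with KRIT1	Q25,H27,I36,E37,D38,S39,Y40,Q43,M67
Other	3T5G	3T5G	Rheb in complex with PDE6D	T2,D57,G178,P179,G180
Other	2BOV	2BOV	Recognition of an ADP-ribosylating Clostridium botulinum C3 exoenzyme by RalA	I139,P140,E143
Other	1UAD	1UAD	Interaction between RalA and Sec5, a subunit of the sec6/8 complex	I36,G48,E49,T50,C51
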