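protein_name	gene_symbol	mw_da	OC3	OECM1	SAS	SCC4	SCC25	E-MEXP-44	E-TABM-302	E-UMCU-11	GDS1062	GDS1584	GDS2520	E-GEOD-13601	GSE9349	GSE9844	signalp	secretomep	tmhmm
Beta-defensin 2	DEFB4	7038		+										+		+	Y	Y	Y
Ubiquitin	RPS27A	8565	+	+		+	+	+								+	N	Y	N
Cyclin-dependent kinases regulatory subunit 1	CKS1B	9660	+	+		+	+	+					+			+	N	N	N
Small nuclear ribonucleoprotein F	SNRPF	9725	+	+	+	+		+									N	N	N
Cyclin-dependent kinases regulatory subunit 2	CKS2	9860	+			+	+	+						+	+		N	N	N
C-X-C motif chemokine 11	CXCL11	10365	+	+			+		+			+		+		+	Y	N	Y
C-C motif chemokine 20	CCL20	10762	+	+	+		+							+		+	Y	Y	N
C-X-C motif chemokine 10	CXCL10	10882	+	+		+	+					+		+		+	Y	Y	Y
Growth-regulated alpha protein	CXCL1	11302	+	+	+	+	+					+		+		+	Y	Y	N
C-X-C motif chemokine 2	CXCL2	11389	+	+	+		+									+	Y	Y	N
High mobility group protein HMGI-C	HMGA2	11832	+			+	+					+				+	N	Y	N
Interferon-induced transmembrane protein 1	IFITM1	13965	+	+	+	+	+					+					N	Y	Y
Histone H2A type 2-A	HIST2H2AA3	14096	+	+	+	+	+						+	+		+	N	N	N
Galectin-1	LGALS1	14716	+	+	+	+	+					+	+				N	N	N
Thymosin beta-10	TMSB10	5026	+	+	+	+	+							+			N	Y	N
Apolipoprotein C-I	APOC1	9332	+	+	+	+	+					+					Y	Y	N
C-C motif chemokine 5	CCL5	9990	+	+		+	+					+		+			Y	Y	Y
BolA-like protein 2	BOLA2	10116	+	+	+	+	+	+						+			N	Y	N
60S ribosomal protein L37a	RPL37A	10275	+			+	+				+						N	Y	N
Protein S100-P	S100P	10400	+	+	+	+	+							+			N	Y	N
10 kDa heat shock protein, mitochondrial	HSPE1	10932	+	+	+	+	+						+				N	Y	N
Protein S100-A2	S100A2	11117	+	+	+	+	+							+			N	N	N
Apolipoprotein A-II	APOA2	11175	+								+						Y	Y	N
C-X-C motif chemokine 3	CXCL3	11343	+	+	+	+	+									+	Y	Y	N
C-X-C motif chemokine 6	CXCL6	11898				+										+	Y	Y	N
Transcription elongation factor B polypeptide 1	TCEB1	12473	+	+	+	+	+	+									N	N	N
Macrophage migration inhibitory factor	MIF	12477	+	+	+	+	+							+			N	Y	N
Lymphocyte antigen 6D	LY6D	13286	+			+	+							+			Y	N	Y
Histone H2A.V	H2AFV	13509	+	+	+	+	+									+	N	Y	N
Serum amyloid A protein	SAA1	13533	+			+	+		+			+				+	Y	Y	N
Histone H2B type 1-C/E/F/G/I	HIST1H2BC	13893	+	+	+	+	+	+					+				N	N	N
Activated RNA polymerase II transcriptional coactivator p15	SUB1	14396	+	+	+	+	+							+			N	Y	N
Fatty acid-binding protein, adipocyte	FABP4	14719					+					+					N	Y	N
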