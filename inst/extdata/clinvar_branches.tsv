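Assembly	GeneSymbol	ClinicalSignificance	ReviewStatus	LastEvaluated	Chromosome	PositionVCF	ReferenceAlleleVCF	AlternateAlleleVCF
GRCh38	BRCA2	Pathogenic	criteria provided, multiple submitters, no conflicts	Jan 01, 2016	13	32316461	G	A
GRCh38	BRCA2	Pathogenic	criteria provided, multiple submitters, no conflicts	Dec 31, 2015	13	32316477	C	T
GRCh38	LDLR	Likely pathogenic	criteria provided, multiple submitters, no conflicts	-	19	11100236	G	A
GRCh38	HBB	Pathogenic	reviewed by expert panel	Jun 01, 2010	11	5227002	T	A
GRCh38	HFE	Pathogenic, risk factor	practice guideline	Jan 15, 2008	6	26092913	G	A
GRCh38	HFE	Conflicting interpretations of pathogenicity	criteria provided, multiple submitters, no conflicts	2020-01-01	6	26090951	C	G
GRCh37	BRCA2	Pathogenic	criteria provided, multiple submitters, no conflicts	2020-01-01	13	32890572	G	A
GRCh38	MUTYH	Uncertain significance	reviewed by expert panel	2020-01-01	1	45331556	C	T
GRCh38	APOB	Pathogenic	criteria provided, single submitter	2020-01-01	2	21006288	C	T
GRCh38	PALB2	Pathogenic/Likely pathogenic	criteria provided, multiple submitters, no conflicts	Mar 01, 2019	16	23635339	C	A
GRCh38	PKP2	Likely pathogenic, risk factor	criteria provided, multiple submitters, no conflicts	2018-07-01	12	32896863	G	T
GRCh38	KCNQ1	Benign	practice guideline	2020-01-01	11	2583474	G	A
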