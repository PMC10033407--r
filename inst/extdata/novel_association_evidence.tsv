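gene	case_set	level	moi	variant_class	pli	z	coseg_relatives	coseg_consistent	biology_support	printed_score
ERG	Primary lymphoedema	specific_disease	dominant	high	0.96	2.53	3	TRUE	TRUE	3
GPR156	Congenital hearing impairment	specific_disease	recessive	high	0	1.04	6	TRUE	TRUE	3
PMEPA1	Familial thoracic aortic aneurysm disease	specific_disease	dominant	high	0.94	1.21	3	TRUE	TRUE	3
FMN1	Congenital hearing impairment	specific_disease	recessive	high	0	-1.53	2	TRUE	TRUE	2
LRRC7	Intellectual disability	specific_disease	dominant	high	1.00	3.60	0	TRUE	TRUE	2
TUFT1	Epidermolysis bullosa	specific_disease	recessive	high	0	0.90	5	TRUE	FALSE	2
USP33	Extreme early-onset hypertension	specific_disease	dominant	high	0.86	2.10	0	TRUE	TRUE	2
ARPC3	Charcot-Marie-Tooth disease	specific_disease	dominant	moderate	0.22	0.39	0	TRUE	TRUE	1
KRT14	Young-onset tumor syndromes	sub_group	recessive	moderate	0	0.84	2	TRUE	FALSE	1
MPPE1	Primary ciliary dyskinesia	specific_disease	recessive	high	0	0.35	2	TRUE	FALSE	1
PKMYT1	Single autosomal recessive mutation in rare disease	specific_disease	recessive	moderate	0.22	0.07	2	TRUE	FALSE	1
RAB35	Familial hypercholesterolemia	specific_disease	dominant	high	0.98	2.36	1	TRUE	FALSE	1
RAB3A	Hereditary ataxia	specific_disease	dominant	moderate	0.95	2.32	0	TRUE	FALSE	1
SERPINB3	Autosomal recessive congenital ichthyosis	specific_disease	recessive	moderate	0	-1.66	2	TRUE	FALSE	1
WWOX	Gastrointestinal disorders	sub_group	recessive	moderate	0	-4.44	1	TRUE	FALSE	1
FAM222B	Ultra-rare undescribed monogenic disorders	specific_disease	dominant	moderate	0.29	0.42	0	TRUE	FALSE	0
INSL4	Rod Dysfunction Syndrome	specific_disease	dominant	moderate	0	-1.43	0	TRUE	FALSE	0
RPL10A	Milroy disease	specific_disease	dominant	high	0.85	2.06	0	TRUE	FALSE	0
SRP9	Ductal plate malformation	specific_disease	dominant	high	0.42	1.13	0	TRUE	FALSE	0
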