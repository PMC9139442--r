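drug	dataset	rho	confidence
AZD6244	GRAY	0.72	High
AZD6244	CCLE	0.42	High
AZD6244	CTRPv2	0.42	High
AZD6244	FIMM	0.28	High
Bortezomib	GRAY	0.68	High
Bortezomib	CTRPv2	0.29	High
Bortezomib	FIMM	0.43	High
Bortezomib	gCSI	0.4	High
Bortezomib	GDSC1000	0.41	High
Bortezomib	Caldas	0.5	High
Docetaxel	GRAY	0.76	High
Docetaxel	CTRPv2	0.8	High
Docetaxel	gCSI	0.48	High
Docetaxel	GDSC1000	0.43	High
Docetaxel	Caldas	0.43	High
Doxorubicin	GRAY	0.78	High
Doxorubicin	FIMM	0.28	High
Doxorubicin	gCSI	0.6	High
Doxorubicin	GDSC1000	-0.05	High
Erlotinib	GRAY	0.76	High
Erlotinib	CCLE	0.41	High
Erlotinib	CTRPv2	0.31	High
Erlotinib	FIMM	-0.09	High
Erlotinib	gCSI	0.57	High
Erlotinib	GDSC1000	0.3	High
Erlotinib	Caldas	-0.13	High
Gefitinib	GRAY	0.74	High
Gefitinib	CTRPv2	0.37	High
Gefitinib	FIMM	0.22	High
Gefitinib	GDSC1000	0.33	High
Gefitinib	Caldas	0.47	High
Gemcitabine	GRAY	0.75	High
Gemcitabine	CTRPv2	0.35	High
Gemcitabine	gCSI	0.48	High
Gemcitabine	GDSC1000	0.19	High
Gemcitabine	Caldas	0.3	High
GSK1059615	GRAY	0.73	High
GSK1059615	CTRPv2	0.49	High
GSK1120212	GRAY	0.78	High
GSK1120212	CTRPv2	0.54	High
GSK1120212	Caldas	0.19	High
GSK461364	GRAY	0.78	High
GSK461364	CTRPv2	0.72	High
Irinotecan	GRAY	0.8	High
Irinotecan	CCLE	0.13	High
Irinotecan	FIMM	-0.13	High
Irinotecan	gCSI	0.57	High
Lapatinib	GRAY	0.77	High
Lapatinib	CCLE	0.68	High
Lapatinib	CTRPv2	0.54	High
Lapatinib	FIMM	0.5	High
Lapatinib	gCSI	0.34	High
Lapatinib	GDSC1000	0.26	High
Lapatinib	Caldas	0.9	High
MG-132	GRAY	0.76	High
MG-132	CTRPv2	0.47	High
MG-132	GDSC1000	0.31	High
Nutlin-3	GRAY	0.74	High
Nutlin-3	CCLE	0.22	High
Nutlin-3	CTRPv2	0.42	High
Paclitaxel	GRAY	0.77	High
Paclitaxel	CCLE	0.36	High
Paclitaxel	CTRPv2	0.61	High
Paclitaxel	FIMM	0.37	High
Paclitaxel	gCSI	0.42	High
Paclitaxel	GDSC1000	0.12	High
Paclitaxel	Caldas	-0.1	High
Panobinostat	GRAY	0.78	High
Panobinostat	CCLE	0.76	High
Panobinostat	CTRPv2	0.6	High
Panobinostat	FIMM	0.72	High
Rapamycin	GRAY	0.7	High
Rapamycin	CTRPv2	0.44	High
Rapamycin	gCSI	-0.17	High
Rapamycin	GDSC1000	-0.05	High
Topotecan	GRAY	0.76	High
Topotecan	CCLE	0.6	High
Topotecan	CTRPv2	0.36	High
Topotecan	FIMM	0.15	High
VX-680	GRAY	0.69	High
VX-680	CTRPv2	0.52	High
VX-680	GDSC1000	0.21	High
ZM-447439	GRAY	0.7	High
ZM-447439	GDSC1000	0.28	High
ZM-447439	Caldas	0.46	High
5-FU	GRAY	0.77	Medium
5-FU	CTRPv2	0.31	Medium
BIBW2992	GRAY	0.79	Medium
BIBW2992	CTRPv2	0.4	Medium
BIBW2992	FIMM	0.39	Medium
BIBW2992	Caldas	0.37	Medium
Cisplatin	GRAY	0.79	Medium
Cisplatin	GDSC1000	0.37	Medium
Cisplatin	Caldas	0.29	Medium
Crizotinib	GRAY	0.75	Medium
Crizotinib	CCLE	0.21	Medium
Crizotinib	CTRPv2	0.36	Medium
Crizotinib	FIMM	-0.04	Medium
Crizotinib	gCSI	0.39	Medium
Crizotinib	GDSC1000	0.03	Medium
Etoposide	GRAY	0.75	Medium
Etoposide	CTRPv2	0.38	Medium
Etoposide	GDSC1000	0.21	Medium
GSK2126458	GRAY	0.73	Medium
GSK2126458	GDSC1000	0.33	Medium
Methotrexate	GRAY	0.74	Medium
Methotrexate	CTRPv2	0.18	Medium
Methotrexate	FIMM	0.09	Medium
Methotrexate	GDSC1000	0.39	Medium
Temsirolimus	GRAY	0.72	Medium
Temsirolimus	FIMM	0.4	Medium
Temsirolimus	GDSC1000	0.1	Medium
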