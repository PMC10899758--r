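hugo_id	pts_I	pts_II	pts_III	pts_IV	pts_V	pts_VI	pts_VII	cmc_score	onco_ts
MIR21	1	1	1	1	1	1	1	7	O
MIR122	0.5	0	1	0	0	1	1	3.5	
MIR101-1	1	1	1	1	1	1	0	6	TS
MIR128-1	0.5	0.5	0.5	0	1	1	0	3.5	
MIR101-2	1	1	1	1	1	1	0	6	TS
MIR128-2	0.5	0.5	0.5	0	1	1	0	3.5	
MIR143	1	1	1	1	1	1	0	6	TS
MIR146A	0.5	0	1	0	1	1	0	3.5	
MIR145	1	1	1	1	1	1	0	6	TS
MIR192	0.5	0.5	0.5	0	1	1	0	3.5	
MIR16-1	1	1	1	0	1	1	1	6	
MIR194-1	0.5	0.5	0.5	0	1	1	0	3.5	
MIR26A1	1	1	1	1	1	1	0	6	TS
MIR194-2	0.5	0.5	0.5	0	1	1	0	3.5	
MIR26A2	1	1	1	1	1	1	0	6	TS
MIR210	0.5	0.5	0.5	0	1	1	0	3.5	O
MIR29C	1	1	1	1	1	1	0	6	TS
MIR224	0.5	0.5	0.5	0	1	1	0	3.5	O
MIR155	1	0.5	1	1	1	1	0	5.5	O
MIR23A	0.5	0.5	0.5	0	1	1	0	3.5	
MIR30A	1	1	0.5	1	1	1	0	5.5	TS
MIR26B	0.5	0.5	0.5	0	1	1	0	3.5	
MIR100	0.5	1	0.5	1	1	1	0	5	TS
MIR27B	0.5	0.5	0.5	0	1	1	0	3.5	
MIR106B	0.5	1	0.5	1	1	1	0	5	O
MIR301A	0.5	0.5	0.5	1	1	0	0	3.5	O
MIR10B	1	1	1	0	1	1	0	5	
MIR32	0.5	0.5	0.5	0	1	1	0	3.5	
MIR126	1	1	1	0	1	1	0	5	
MIR335	0.5	0.5	0.5	0	1	1	0	3.5	
MIR15A	0.5	0.5	1	0	1	1	1	5	
MIR342	0	1	0.5	0	1	1	0	3.5	
MIR16-2	1	1	1	0	1	1	0	5	
MIR497	1	1	0.5	1	0	0	0	3.5	TS
MIR17	1	1	1	0	1	1	0	5	O
MIR96	0.5	0.5	0.5	0	1	1	0	3.5	O
MIR181A1	1	1	1	0	1	1	0	5	
MIRLET7E	0	0.5	1	0	1	1	0	3.5	TS
MIR181A2	1	1	1	0	1	1	0	5	
MIRLET7I	0	0.5	1	0	1	1	0	3.5	
MIR199A1	1	1	1	0	1	1	0	5	
MIR103A1	0	0.5	0.5	0	1	1	0	3	O
MIR199A2	1	1	1	0	1	1	0	5	
MIR103A2	0	0.5	0.5	0	1	1	0	3	O
MIR19A	1	0.5	0.5	1	1	1	0	5	O
MIR107	0.5	0	0.5	0	1	1	0	3	
MIR205	1	0	1	0	1	1	1	5	
MIR10A	0.5	0	0.5	0	1	1	0	3	
MIR221	1	1	1	0	1	1	0	5	
MIR124-1	1	0	1	0	0	1	0	3	
MIR29B1	1	1	1	0	1	1	0	5	
MIR124-2	1	0	1	0	0	1	0	3	
MIR29B2	1	1	1	0	1	1	0	5	
MIR124-3	1	0	1	0	0	1	0	3	
MIR30E	0.5	1	0.5	1	1	1	0	5	
MIR130B	0.5	1	0.5	0	1	0	0	3	
MIR31	1	1	1	0	1	1	0	5	
MIR133B	0.5	0	0.5	1	0	1	0	3	TS
MIR34A	1	1	1	0	1	1	0	5	
MIR144	0.5	1	0.5	0	1	0	0	3	TS
MIR99A	0.5	1	0.5	1	1	1	0	5	TS
MIR148A	1	0.5	0.5	0	1	0	0	3	
MIRLET7B	0.5	0.5	1	1	1	1	0	5	TS
MIR152	0.5	0	0.5	0	1	1	0	3	
MIRLET7C	0.5	0.5	1	1	1	1	0	5	TS
MIR193B	0	0.5	0.5	0	1	1	0	3	
MIR133A1	1	0.5	1	1	0	1	0	4.5	TS
MIR199B	0	0.5	0.5	0	1	1	0	3	
MIR133A2	1	0.5	1	1	0	1	0	4.5	TS
MIR204	1	0.5	0.5	1	0	0	0	3	TS
MIR141	1	1	0.5	0	1	1	0	4.5	
MIR218-1	1	0.5	0.5	0	1	0	0	3	TS
MIR183	1	1	0.5	0	1	1	0	4.5	O
MIR218-2	1	0.5	0.5	0	1	0	0	3	TS
MIR195	1	1	0.5	1	0	1	0	4.5	TS
MIR23B	0.5	0	0.5	0	1	1	0	3	
MIR200A	0.5	1	1	0	1	1	0	4.5	
MIR24-1	0.5	1	0.5	0	1	0	0	3	
MIR200B	0.5	1	1	0	1	1	0	4.5	
MIR24-2	0.5	1	0.5	0	1	0	0	3	
MIR200C	1	0.5	1	0	1	1	0	4.5	
MIR28	0	1	0	0	1	1	0	3	
MIR203A	1	0.5	1	0	1	1	0	4.5	
MIR30B	0	0.5	0.5	0	1	1	0	3	
MIR20A	1	1	0.5	0	1	1	0	4.5	O
MIR30D	0	0.5	0.5	0	1	1	0	3	
MIR222	1	0.5	1	0	1	1	0	4.5	O
MIR324	0	1	0	0	1	1	0	3	
MIR29A	1	0.5	1	0	1	1	0	4.5	
MIR378A	0.5	1	0.5	0	1	0	0	3	
MIR30C1	0	1	0.5	1	1	1	0	4.5	TS
MIR93	0.5	1	0.5	0	1	0	0	3	O
MIR30C2	0	1	0.5	1	1	1	0	4.5	TS
MIRLET7G	0	0	1	0	1	1	0	3	
MIR451A	0.5	0.5	0.5	1	1	1	0	4.5	TS
MIR129-1	0.5	0.5	0.5	0	0	1	0	2.5	TS
MIR7-1	0.5	1	1	0	1	1	0	4.5	
MIR129-2	0.5	0.5	0.5	0	0	1	0	2.5	TS
MIR7-2	0.5	1	1	0	1	1	0	4.5	
MIR130A	0.5	0.5	0.5	0	1	0	0	2.5	
MIR7-3	0.5	1	1	0	1	1	0	4.5	
MIR135B	0.5	0.5	0.5	0	0	1	0	2.5	O
MIR9-1	1	0.5	1	0	1	1	0	4.5	
MIR137	1	0	0.5	0	0	1	0	2.5	
MIR9-2	1	0.5	1	0	1	1	0	4.5	
MIR146B	0.5	0.5	0.5	0	1	0	0	2.5	
MIR92A1	1	1	0.5	0	1	1	0	4.5	
MIR181C	0	0	0.5	0	1	1	0	2.5	
MIR92A2	1	1	0.5	0	1	1	0	4.5	
MIR193A	0	1	0.5	0	1	0	0	2.5	
MIR9-3	1	0.5	1	0	1	1	0	4.5	
MIR22	0.5	0.5	0.5	0	1	0	0	2.5	
MIRLET7A1	1	0.5	1	0	1	1	0	4.5	
MIR34B	0.5	0	1	0	0	1	0	2.5	
MIRLET7A2	1	0.5	1	0	1	1	0	4.5	
MIR34C	0.5	0	1	0	0	1	0	2.5	
MIRLET7A3	1	0.5	1	0	1	1	0	4.5	
MIR423	0	0.5	0	0	1	1	0	2.5	
MIR1-1	0.5	0.5	1	1	0	1	0	4	TS
MIR455	0.5	1	0	0	1	0	0	2.5	
MIR1-2	0.5	0.5	1	1	0	1	0	4	TS
MIR106A	0.5	0.5	0	0	1	0	0	2	
MIR125A	0.5	1	0.5	0	1	1	0	4	TS
MIR132	0.5	0.5	0	0	1	0	0	2	
MIR125B1	1	1	1	0	0	1	0	4	
MIR135A1	0.5	0	0.5	0	0	1	0	2	
MIR125B2	1	1	1	0	0	1	0	4	
MIR135A2	0.5	0	0.5	0	0	1	0	2	
MIR139	0.5	1	0.5	1	1	0	0	4	TS
MIR138-1	1	0.5	0.5	0	0	0	0	2	TS
MIR140	0.5	1	0.5	1	1	0	0	4	TS
MIR138-2	1	0.5	0.5	0	0	0	0	2	TS
MIR142	0.5	1	0.5	0	1	0	1	4	
MIR148B	0.5	0	0.5	0	1	0	0	2	
MIR150	1	0.5	0.5	0	1	1	0	4	
MIR149	0	0.5	0.5	0	1	0	0	2	
MIR15B	0.5	1	0.5	0	1	1	0	4	
MIR206	0.5	0	0.5	0	0	1	0	2	TS
MIR181B1	0.5	0.5	1	0	1	1	0	4	
MIR215	0.5	0	0.5	0	0	1	0	2	
MIR181B2	0.5	0.5	1	0	1	1	0	4	
MIR320A	0.5	0	0.5	0	1	0	0	2	
MIR182	1	1	1	0	1	0	0	4	O
MIR331	0	0.5	0.5	0	0	1	0	2	
MIR18A	0.5	1	0.5	0	1	1	0	4	O
MIR345	0	0	0	0	1	1	0	2	
MIR19B1	0.5	1	0.5	0	1	1	0	4	
MIR373	0.5	0	0.5	0	0	1	0	2	
MIR19B2	0.5	1	0.5	0	1	1	0	4	
MIR449A	0.5	0	0.5	0	0	1	0	2	
MIR214	1	0.5	0.5	0	1	1	0	4	
MIR483	0	0.5	0.5	0	0	1	0	2	
MIR223	1	0.5	0.5	0	1	1	0	4	
MIR486-1	0.5	0.5	0	0	1	0	0	2	TS
MIR25	0.5	1	0.5	0	1	1	0	4	O
MIR486-2	0.5	0.5	0	0	1	0	0	2	TS
MIR27A	1	0.5	0.5	0	1	1	0	4	
MIR494	0.5	0	0.5	0	0	1	0	2	
MIR375	1	0	1	0	1	1	0	4	
MIR625	0	0	0	0	1	1	0	2	
MIRLET7D	0.5	0.5	1	0	1	1	0	4	
MIR98	0.5	0	0.5	0	1	0	0	2	
MIRLET7F1	0.5	0.5	1	0	1	1	0	4	
MIR99B	0	0.5	0.5	0	1	0	0	2	
MIRLET7F2	0.5	0.5	1	0	1	1	0	4	
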