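node_no	node_name	min_C1	min_C2	min_C3	max_C1	max_C2	max_C3
1	Great Oxidation Event	2320	2320	2320	3000	3000	3000
2	Earliest cyanobacteria	1900	1900	1900	3000	3000	3000
3	Pleurocapsales	1700	1640	1640	1900	3000	3000
4	Nostocales	1600	1580	1580	1900	3000	3000
5	Richelia	110	110	110	3000	3000	3000
6	Earliest Rhodophyta	1050	1030	1560	3000	2300	2300
7	Floridiophyceae	600	595	595	3000	2300	2300
8	Earliest diatom	190	185	185	3000	2300	2300
9	Bacillariophytina	110	110	110	3000	2300	2300
10	Ulvophyceae	635	948	948	3000	2300	2300
11	Earliest land plants	475	471	471	501	515	515
12	Tracheophyta	446	446	446	501	515	515
13	Angiosperms/Gymnosperms	385	385	385	501	515	515
14	Angiosperms	130	130	130	501	515	515
15	Eudicots	125	125	125	501	515	515
16	Zygnemataceae	345	345	345	3000	2300	2300
17	Gymnosperms	385	385	385	501	515	515
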