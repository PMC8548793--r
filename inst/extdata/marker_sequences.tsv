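marker	nominal	sequence	taxon	reconciles	hydroxylations	computed_mz
P1	1120	GVQGPAGPQGPR	NA	TRUE	0	1120.585751
P1	1162	GVQGPPGPQGPR	NA	TRUE	1	1162.596311
A	1137	PGNAGAVGPAGLR	NA	TRUE	0	1136.6170410000002
A	1150	PGQAGAVGPAGLR	NA	TRUE	0	1150.632691
A	1159	PGHAGAVGPAGLR	NA	TRUE	0	1159.633021
A	1182	SGQPGTVGPAGVR	NA	TRUE	0	1182.6225310000002
B	1397	GVAGEFGLPGPAGPR	NA	TRUE	1	1397.7171309999999
B	1411	GPAGEFGLPGPAGPR	NA	TRUE	2	1411.6963910000002
B	1427	GSPGEFGLPGPAGPR	NA	TRUE	2	1427.691311
B	1439	GVPGEFGLPGPAGPR	NA	TRUE	2	1439.727691
B	1453	GLPGEFGLPGPAGPR	NA	TRUE	2	1453.743341
C	1598	GPPGESGAVGPTGSIGSR	NA	TRUE	1	1598.776841
C	1607	GPPGESGAAGPTGPLGNR	NA	TRUE	1	1607.777171
P2	1650	GPNGEPGSTGPSGPPGLR	NA	TRUE	1	1649.787741
P2	1680	GPNGEPGSTGPTGPPGLR	NA	TRUE	2	1679.798301
P2	1692	GPNGEPGSTGPPGPPGLR	NA	TRUE	3	1691.798291
P2	1725	GPNGEPGSTGPMGPPGLR	NA	TRUE	3	1725.786021
D	2119	GLPGVSGSLGEPGPLGIAGPAGAR	NA	TRUE	2	2119.1141209999996
D	2121	GLPGVSGGLGEPGPLGLSGPSGAR	Tachyglossus aculeatus	TRUE	2	2121.0933909999994
D	2121	GLPGVSGSVGEPGPLGIAGPAGAR	Thylacinus cynocephalus	TRUE	3	2121.093381
D	2145	GLPGVSGALGEPGPLGIAGPPGAR	NA	TRUE	3	2145.129761
D	2161	GLPGVSGSLGEPGPLGIAGPPGAR	NA	TRUE	3	2161.124681
D	2163	GLPGVSGSVGEPGPLGISGPPGAR	NA	TRUE	3	2163.103951
D	2177	GLPGVSGSLGEPGPLGISGPPGAR	NA	TRUE	3	2177.119601
E	2335	GEQGPAGPPGFQGLPGPSGPAGEGGK	NA	TRUE	2	2335.0948409999996
E	2848	GEQGPAGPPGFQGLPGPSGPAGEVGKPGER	NA	TRUE	4	2848.349531
F	2869	GLTGPIGPPGPAGPSGDKGESGPSGPAGPTGAR	NA	TRUE	1	2869.4073909999997
F	2873	GLTGPIGPPGPAGTSGDKGESGPSGPAGPTGAR	NA	TRUE	1	2873.402311
F	2881	GLTGPIGPPGPAGPAGDKGESGPSGPVGPTGAR	NA	TRUE	1	2881.4437709999997
F	2897	GLTGPIGPPGPAGPSGDKGESGPSGPVGPTGAR	NA	TRUE	1	2897.438691
G	2929	GPPGEAGASGPPGSSGPQGLLGAPGILGLPGSR	NA	TRUE	4	2929.464891
G	2943	GPPGEAGATGPPGSSGPQGLLGAPGILGLPGSR	NA	TRUE	4	2943.480541
G	2945	GPEGEAGASGPPGSSGPQGLLGAPGILGLPGSR	NA	TRUE	3	2945.459811
G	2957	GPPGESGAVGPPGSSGPQGLLGAPGILGLPGSR	NA	TRUE	4	2957.4961909999997
G	2959	GPPGESGATGPPGSSGPQGLLGAPGILGLPGSR	NA	TRUE	4	2959.475461
G	2971	GPPGESGALGPPGSSGPQGLLGAPGILGLPGSR	NA	TRUE	4	2971.511841
G	2999	GPPGEAGATGPPGSSGPQGLWGAPGILGLPGSR	NA	FALSE	NA	NA
COL1A2 10-42	2975	GPPGASGPPGAQGFQGPAGEPGEPGQTGPAGAR	NA	TRUE	4	2975.351321
COL1A2 10-42	2989	GPPGATGPPGAQGFQGPAGEPGEPGQTGPAGAR	NA	TRUE	4	2989.366971
COL1A2 10-42	2991	GPPGASGPPGAQGFQGPAGEPGEPGQTGPAGSR	NA	TRUE	4	2991.3462409999997
COL1A2 10-42	3009	GPPGASGPPGAQGFQGPAGEPGEDGQTGPAGAR	NA	TRUE	5	3009.3204109999997
COL1A2 889-906	1606	GEPGPVGSVGPVGPTGAR	NA	TRUE	1	1606.818301
COL1A2 889-906	1624	GEPGPAGSVGPVGPFGAR	NA	TRUE	1	1624.807731
COL1A2 889-906	1652	GEPGPVGSVGPVGPFGAR	NA	TRUE	1	1652.839031
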