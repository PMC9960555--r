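# Stable-isotope masses (u) and natural abundances (mole fraction).
# Values follow the IUPAC/CIAAW 2013-2021 recommendations (representative
# single values; abundance normalised per element). This table is bundled so
# that every mass in the package is version-pinned to one reference set.
# Columns: element, nominal mass, isotopic mass (u), abundance.
element	nominal	mass	abundance
H	1	1.0078250319	0.999885
H	2	2.0141017781	0.000115
C	12	12.0000000000	0.9893
C	13	13.0033548350	0.0107
N	14	14.0030740052	0.99636
N	15	15.0001088984	0.00364
O	16	15.9949146221	0.99757
O	17	16.9991315000	0.00038
O	18	17.9991604000	0.00205
F	19	18.9984032000	1.0
Na	23	22.9897692800	1.0
Si	28	27.9769265300	0.92223
Si	29	28.9764946600	0.04685
Si	30	29.9737700100	0.03092
P	31	30.9737615100	1.0
S	32	31.9720706900	0.9499
S	33	32.9714585000	0.0075
S	34	33.9678668300	0.0425
S	36	35.9670808800	0.0001
Cl	35	34.9688527100	0.7576
Cl	37	36.9659026000	0.2424
K	39	38.9637066800	0.932581
K	40	39.9639984800	0.000117
K	41	40.9618257600	0.067302
Br	79	78.9183376000	0.5069
Br	81	80.9162906000	0.4931
I	127	126.9044730000	1.0
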