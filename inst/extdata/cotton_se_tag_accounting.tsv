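label	clean	unambiguous	unambiguous_genes	unknown
0h	3713673	1551964	13446	1994178
6h	3574921	1361344	13513	2093782
24h	3421294	1393380	13781	1891802
48h	3433665	1239777	12595	1970515
NEC	3649041	1423394	12687	2013798
EC	3542887	1237924	12230	2185187
GE	3542767	1333449	12406	2113500
TE	3662505	1427168	12749	2134578
CE	3567705	1258997	12649	2162331
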