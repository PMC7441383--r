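rank	y	score	label	cuis	categories
1	lamotrigine	0.385201	Tx	C0064636	Tx_therapeutic
2	carbamazepine	0.345227	Tx	C0006949	Tx_adverse
3	low_propensity	0.324285	non-Tx		
4	clonazepam	0.310706	Tx	C0009011	Tx_uncertain
5	topiramate	0.308402	Tx	C0076829	Tx_therapeutic
6	lithium_valproate	0.308223	Tx	C0023870|C0080356	Tx_therapeutic|Tx_adverse
7	clobazam	0.306901	Tx	C0055891	Tx_therapeutic
8	sodium_valproate	0.300513	Tx	C0037567	Tx_therapeutic
9	lorazepam	0.29562	Tx	C0024002	Tx_therapeutic
10	lithium	0.294804	Tx	C0023870	Tx_therapeutic|Tx_adverse
11	gabapentin_pregabalin_topiramate	0.291698	Tx	C0657912|C0076829|C0060926	Tx_therapeutic
12	antiepileptic_drugs_other_than	0.290046	Tx	C0003299	Tx_therapeutic
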