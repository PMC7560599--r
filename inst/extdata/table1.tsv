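sample_id	karyotype	sex	age	elapsed_months	induction	maintenance	pathway
1305	11;14	Male	51	38.34	CTD	No	Intensive
1334	11;14	Female	43	24.00	CTD	Missing	Intensive
5834	11;14	Female	69	29.93	CTDa	No	Nonintensive
6030	4;14	Female	36	19.75	CTD	No	Intensive
6178	11;14	Female	67	18.40	RCD	Missing	Intensive
6229	11;14	Male	74	9.23	CTDa	Missing	Nonintensive
6706	11;14	Male	59	25.43	RCD	No	Intensive
6988	11;14	Male	69	12.26	RCDa	No	Nonintensive
7020	4;14	Female	58	14.69	CTD	Missing	Intensive
7240	4;14	Male	55	11.30	RCD	Lenalidomide	Intensive
7801	14;16	Female	48	14.49	CTD	Missing	Intensive
7842	4;14	Male	66	17.64	CTD	No	Intensive
8237	4;14	Female	49	14.00	CTD	No	Intensive
9126	11;14	Male	64	16.23	CTDa	Missing	Nonintensive
9166	14;16	Female	68	27.24	CCRD	No	Intensive
9515	11;14	Male	68	26.15	RCDa	Lenalidomide	Nonintensive
9721	14;16	Male	64	29.44	CTD	Lenalidomide	Intensive
10068	4;14	Male	71	13.77	RCDa	Lenalidomide and Vorinostat	Nonintensive
10365	11;14	Male	76	9.33	CTD	Missing	Intensive
11506	14;16	Male	77	11.83	CTDa	Lenalidomide	Nonintensive
11668	4;14	Male	49	19.29	RCDa	Missing	Nonintensive
11949	11;14	Male	76	14.65	CTD	Missing	Intensive
12546	4;14	Male	77	30.59	RCD	Missing	Intensive
13029	4;14	Male	62	6.90	CTD	Missing	Intensive
5695	11;14	Male	64	NA	CTD	No	Intensive
5699	11;14	Female	68	NA	CTD	Missing	Intensive
5836	11;14	Male	77	NA	CTDa	No	Nonintensive
5939	4;14	Male	65	NA	CTD	Missing	Intensive
6016	11;14	Female	55	NA	RCD	Missing	Intensive
6076	4;14	Male	72	NA	RCDa	Lenalidomide	Nonintensive
6163	4;14	Male	75	NA	RCDa	Missing	Nonintensive
6277	11;14	Male	56	NA	RCD	Lenalidomide	Intensive
6279	4;14	Male	62	NA	RCD	Lenalidomide	Intensive
6345	4;14	Female	72	NA	CTDa	Missing	Nonintensive
6415	11;14	Female	68	NA	RCDa	Missing	Nonintensive
6425	4;14	Male	67	NA	RCD	Lenalidomide and Vorinostat	Intensive
6501	11;14	Female	51	NA	RCD	Missing	Intensive
6702	4;14	Female	78	NA	CTDa	Missing	Nonintensive
7000	11;14	Female	78	NA	CTDa	Missing	Nonintensive
7005	4;14	Male	74	NA	CTDa	Missing	Nonintensive
7164	11;14	Female	80	NA	RCDa	Missing	Nonintensive
7348	4;14	Male	67	NA	RCDa	No	Nonintensive
7729	4;14	Male	65	NA	RCD	Lenalidomide and Vorinostat	Intensive
7794	4;14	Female	52	NA	CTD	No	Intensive
7880	4;14	Female	82	NA	RCDa	Missing	Non-intensive
7915	4;14	Male	59	NA	CTD	Lenalidomide and Vorinostat	Intensive
7925	4;14	Male	59	NA	CTD	Missing	Intensive
7950	4;14	Male	49	NA	CTD	Lenalidomide and Vorinostat	Intensive
7956	4;14	Female	56	NA	CTD	Missing	Intensive
8043	4;14	Female	81	NA	CTDa	Missing	Non-intensive
8245	11;14	Female	63	NA	RCD	Lenalidomide	Intensive
8567	11;14	Female	66	NA	RCDa	Lenalidomide and Vorinostat	Nonintensive
8573	4;14/HD	Female	82	NA	CTDa	Missing	Nonintensive
8928	4;14	Male	52	NA	CTD	Missing	Intensive
8979	4;14	Male	76	NA	CTDa	Missing	Nonintensive
9069	11;14	Male	73	NA	RCDa	Missing	Non-intensive
9176	11;14	Male	78	NA	RCDa	Missing	Nonintensive
9210	11;14	Male	69	NA	CTD	Missing	Intensive
9249	11;14	Male	58	NA	RCD	Lenalidomide	Intensive
9289	11;14	Male	56	NA	CTD	No	Intensive
9292	4;14	Female	74	NA	CTDa	Missing	Nonintensive
9337	11;14	Female	71	NA	CTDa	Missing	Nonintensive
9376	4;14	Female	64	NA	RCD	Missing	Intensive
9409	11;14	Male	73	NA	CTDa	Missing	Nonintensive
9524	4;14	Male	51	NA	RCDa	Lenalidomide	Nonintensive
9544	11;14	Male	67	NA	RCDa	No	Nonintensive
9623	11;14	Male	58	NA	RCD	Lenalidomide	Intensive
9718	4;14	Male	66	NA	RCDa	No	Nonintensive
9917	11;14	Male	76	NA	CTDa	Missing	Nonintensive
9931	11;14	Female	55	NA	RCD	Missing	Intensive
10085	11;14	Female	59	NA	CCRD	Lenalidomide	Intensive
10212	11;14	Female	79	NA	RCDa	Lenalidomide	Nonintensive
10597	4;14	Male	59	NA	CCRD	No	Intensive
10772	4;14	Female	63	NA	CCRD	Missing	Intensive
10801	11;14	Male	77	NA	RCDa	Missing	Nonintensive
11029	4;14	Female	73	NA	RCDa	Missing	Nonintensive
11897	4;14	Male	58	NA	CCRD	Lenalidomide	Intensive
12101	4;14	Male	62	NA	CCRD	Missing	Intensive
12227	11;14	Male	57	NA	CCRD	No	Intensive
12541	11;14	Male	56	NA	CTD	Missing	Intensive
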