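analysis_id	proband_id	strategy	informative
A001	T01	ES-Trio	1
A002	T02	ES-Trio	1
A003	T03	ES-Trio	1
A004	T04	ES-Trio	1
A005	T05	ES-Trio	1
A006	T06	ES-Trio	1
A007	T07	ES-Trio	1
A008	T08	ES-Trio	1
A009	T09	ES-Trio	1
A010	T10	ES-Trio	1
A011	T11	ES-Trio	1
A012	T12	ES-Trio	1
A013	T13	ES-Trio	1
A014	T14	ES-Trio	1
A015	T15	ES-Trio	1
A016	T16	ES-Trio	1
A017	T17	ES-Trio	1
A018	T18	ES-Trio	1
A019	T19	ES-Trio	1
A020	T20	ES-Trio	1
A021	T21	ES-Trio	1
A022	T22	ES-Trio	1
A023	T23	ES-Trio	1
A024	T24	ES-Trio	1
A025	T25	ES-Trio	1
A026	T26	ES-Trio	1
A027	T27	ES-Trio	1
A028	T28	ES-Trio	1
A029	T29	ES-Trio	1
A030	T30	ES-Trio	1
A031	T31	ES-Trio	1
A032	T32	ES-Trio	1
A033	T33	ES-Trio	0
A034	T34	ES-Trio	0
A035	T35	ES-Trio	0
A036	T36	ES-Trio	0
A037	T37	ES-Trio	0
A038	T38	ES-Trio	0
A039	T39	ES-Trio	0
A040	T40	ES-Trio	0
A041	T41	ES-Trio	0
A042	T42	ES-Trio	0
A043	T43	ES-Trio	0
A044	T44	ES-Trio	0
A045	T45	ES-Trio	0
A046	T46	ES-Trio	0
A047	T47	ES-Trio	0
A048	T48	ES-Trio	0
A049	T49	ES-Trio	0
A050	T50	ES-Trio	0
A051	T51	ES-Trio	0
A052	T52	ES-Trio	0
A053	T53	ES-Trio	0
A054	T54	ES-Trio	0
A055	T55	ES-Trio	0
A056	T56	ES-Trio	0
A057	T57	ES-Trio	0
A058	T58	ES-Trio	0
A059	T59	ES-Trio	0
A060	T60	ES-Trio	0
A061	T61	ES-Trio	0
A062	T62	ES-Trio	0
A063	T63	ES-Trio	0
A064	T64	ES-Trio	0
A065	T65	ES-Trio	0
A066	T66	ES-Trio	0
A067	T67	ES-Trio	0
A068	T68	ES-Trio	0
A069	T69	ES-Trio	0
A070	T70	ES-Trio	0
A071	T71	ES-Trio	0
A072	D01	ES-Duo	1
A073	D02	ES-Duo	1
A074	D03	ES-Duo	0
A075	D04	ES-Duo	0
A076	D05	ES-Duo	0
A077	D06	ES-Duo	0
A078	D07	ES-Duo	0
A079	S01	ES-Solo	1
A080	S02	ES-Solo	1
A081	S03	ES-Solo	1
A082	S04	ES-Solo	1
A083	S05	ES-Solo	1
A084	S06	ES-Solo	1
A085	S07	ES-Solo	1
A086	S08	ES-Solo	1
A087	S09	ES-Solo	1
A088	S10	ES-Solo	0
A089	S11	ES-Solo	0
A090	S12	ES-Solo	0
A091	S13	ES-Solo	0
A092	S14	ES-Solo	0
A093	S15	ES-Solo	0
A094	S16	ES-Solo	0
A095	S17	ES-Solo	0
A096	S18	ES-Solo	0
A097	S19	ES-Solo	0
A098	S01	CES	0
A099	S02	CES	0
A100	S03	CES	0
A101	S04	CES	0
A102	S05	CES	0
A103	S06	CES	0
A104	S07	CES	0
A105	S08	CES	0
A106	S09	CES	0
A107	S10	CES	0
A108	C01	CES	1
A109	C02	CES	1
A110	C03	CES	1
A111	C04	CES	1
A112	C05	CES	0
A113	C06	CES	0
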