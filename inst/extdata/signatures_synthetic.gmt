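mes15	Mes 15-gene panel (placeholder identities; exemplar stromal genes plus canonical CAF genes) [synthetic]	POSTN	COL11A1	LOX	VCAN	TNC	THBS2	FAP	COL1A1	COL5A1	COL5A2	COL10A1	FN1	SPARC	INHBA	FBN1
mes100	Mes 100-gene list (synthetic placeholder)	POSTN	COL11A1	LOX	VCAN	TNC	THBS2	FAP	COL1A1	COL5A1	COL5A2	COL10A1	FN1	SPARC	INHBA	FBN1	MESX001	MESX002	MESX003	MESX004	MESX005	MESX006	MESX007	MESX008	MESX009	MESX010	MESX011	MESX012	MESX013	MESX014	MESX015	MESX016	MESX017	MESX018	MESX019	MESX020	MESX021	MESX022	MESX023	MESX024	MESX025	MESX026	MESX027	MESX028	MESX029	MESX030	MESX031	MESX032	MESX033	MESX034	MESX035	MESX036	MESX037	MESX038	MESX039	MESX040	MESX041	MESX042	MESX043	MESX044	MESX045	MESX046	MESX047	MESX048	MESX049	MESX050	MESX051	MESX052	MESX053	MESX054	MESX055	MESX056	MESX057	MESX058	MESX059	MESX060	MESX061	MESX062	MESX063	MESX064	MESX065	MESX066	MESX067	MESX068	MESX069	MESX070	MESX071	MESX072	MESX073	MESX074	MESX075	MESX076	MESX077	MESX078	MESX079	MESX080	MESX081	MESX082	MESX083	MESX084	MESX085
primary_stroma	Primary ovarian HGSC 21-gene stromal signature (synthetic placeholder)	GSTA2	PSTR01	PSTR02	PSTR03	PSTR04	PSTR05	PSTR06	PSTR07	PSTR08	PSTR09	PSTR10	PSTR11	PSTR12	PSTR13	PSTR14	PSTR15	PSTR16	PSTR17	PSTR18	PSTR19	PSTR20
omental_stroma	Omental metastasis 21-gene stromal signature (synthetic placeholder)	LPREL2	OMST01	OMST02	OMST03	OMST04	OMST05	OMST06	OMST07	OMST08	OMST09	OMST10	OMST11	OMST12	OMST13	OMST14	OMST15	OMST16	OMST17	OMST18	OMST19	OMST20
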