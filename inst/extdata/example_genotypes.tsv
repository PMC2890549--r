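subject_id	rs334348	rs334349	rs1590	rs7871490	sig9A6A
S001	0	1	0	0	1
S002	0	0	1	1	1
S003	0	0	0	1	1
S004	1	1	0	0	1
S005	0	1	0	0	1
S006	0	0	1	0	1
S007	0	0	0	1	0
S008	1	0	0	0	0
S009	0	1	1	0	0
S010	0	0	1	1	0
S011	1	0	0	1	0
S012	1	0	0	0	0
S013	0	1	0	0	0
S014	0	0	1	0	0
S015	0	0	0	1	0
S016	1	0	0	0	0
S017	0	1	1	0	0
S018	0	0	1	1	0
S019	0	0	0	1	0
S020	1	1	0	0	0
S021	0	1	1	0	0
S022	0	0	1	1	0
S023	0	0	0	1	0
S024	1	0	0	0	0
S025	0	1	0	0	0
S026	0	0	1	0	0
S027	0	0	0	1	0
S028	1	0	0	0	0
S029	0	1	0	0	0
S030	0	0	1	0	0
S031	0	0	0	1	1
S032	1	1	0	0	0
S033	0	1	1	0	0
S034	0	0	1	0	0
S035	1	0	0	1	0
S036	1	0	0	0	0
S037	0	1	0	0	1
S038	0	0	1	1	0
S039	0	0	0	1	0
S040	1	0	0	0	0
S041	0	1	0	0	0
S042	0	0	1	0	0
S043	0	0	0	1	1
S044	1	0	0	0	0
S045	0	1	0	0	0
S046	0	0	1	0	0
S047	0	0	0	1	0
S048	1	0	0	0	0
S049	0	1	0	0	0
S050	0	0	1	0	0
S051	0	0	0	1	0
S052	1	1	0	0	0
S053	0	1	0	0	0
S054	0	0	1	1	0
S055	1	0	0	1	0
S056	1	0	0	0	0
S057	0	1	0	0	0
S058	0	0	1	1	0
S059	1	0	0	1	0
S060	1	0	0	0	0
S061	0	1	0	0	0
S062	0	0	1	0	0
S063	0	0	0	1	0
S064	1	0	0	0	0
S065	0	1	1	0	0
S066	0	0	1	0	0
S067	0	0	0	1	0
S068	1	0	0	0	0
S069	0	1	0	0	0
S070	0	0	1	0	0
S071	0	0	0	1	0
S072	1	0	0	0	1
S073	0	1	0	0	0
S074	0	0	1	0	0
S075	0	0	0	0	0
S076	0	0	0	0	0
S077	0	0	0	0	0
S078	0	0	0	0	0
S079	0	0	0	0	0
S080	0	0	0	0	0
S081	0	0	0	0	0
S082	0	0	0	0	0
S083	0	0	0	0	0
S084	0	0	0	0	0
S085	0	0	0	0	0
S086	0	0	0	0	0
S087	0	0	0	0	0
S088	0	0	0	0	1
S089	0	0	0	0	0
S090	0	0	0	0	0
S091	0	0	0	0	0
S092	0	0	0	0	0
S093	0	0	0	0	0
S094	0	0	0	0	0
S095	0	0	0	0	0
S096	0	0	0	0	0
S097	0	0	0	0	0
S098	0	0	0	0	0
S099	0	0	0	0	0
S100	0	0	0	0	0
S101	0	0	0	0	0
S102	0	0	0	0	1
S103	0	0	0	0	0
S104	0	0	0	0	1
S105	0	0	0	0	0
S106	0	0	0	0	0
S107	0	0	0	0	0
S108	0	0	0	0	1
S109	0	0	0	0	0
S110	0	0	0	0	0
S111	0	0	0	0	0
S112	0	0	0	0	0
S113	0	0	0	0	0
S114	0	0	0	0	0
S115	0	0	0	0	0
S116	0	0	0	0	1
S117	0	0	0	0	0
S118	0	0	0	0	0
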