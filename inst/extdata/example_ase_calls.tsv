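subject_id	call
S001	positive
S002	positive
S003	positive
S004	positive
S005	positive
S006	positive
S007	positive
S008	positive
S009	positive
S010	positive
S011	positive
S012	negative
S013	negative
S014	negative
S015	negative
S016	negative
S017	negative
S018	negative
S019	negative
S020	negative
S021	negative
S022	negative
S023	negative
S024	negative
S025	negative
S026	negative
S027	negative
S028	negative
S029	negative
S030	negative
S031	negative
S032	negative
S033	negative
S034	negative
S035	negative
S036	negative
S037	negative
S038	negative
S039	negative
S040	negative
S041	negative
S042	negative
S043	negative
S044	negative
S045	negative
S046	negative
S047	negative
S048	negative
S049	negative
S050	negative
S051	negative
S052	negative
S053	negative
S054	negative
S055	negative
S056	negative
S057	negative
S058	negative
S059	negative
S060	negative
S061	negative
S062	negative
S063	negative
S064	negative
S065	negative
S066	negative
S067	negative
S068	negative
S069	negative
S070	negative
S071	negative
S072	negative
S073	negative
S074	negative
S075	uninformative
S076	uninformative
S077	uninformative
S078	uninformative
S079	uninformative
S080	uninformative
S081	uninformative
S082	uninformative
S083	uninformative
S084	uninformative
S085	uninformative
S086	uninformative
S087	uninformative
S088	uninformative
S089	uninformative
S090	uninformative
S091	uninformative
S092	uninformative
S093	uninformative
S094	uninformative
S095	uninformative
S096	uninformative
S097	uninformative
S098	uninformative
S099	uninformative
S100	uninformative
S101	uninformative
S102	uninformative
S103	uninformative
S104	uninformative
S105	uninformative
S106	uninformative
S107	uninformative
S108	uninformative
S109	uninformative
S110	uninformative
S111	uninformative
S112	uninformative
S113	uninformative
S114	uninformative
S115	uninformative
S116	uninformative
S117	uninformative
S118	uninformative
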