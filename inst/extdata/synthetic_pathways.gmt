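synthetic_pathway_A	synthetic: first chain segment	GENE001	GENE002	GENE003	GENE004	GENE005	GENE006	GENE007	GENE008	GENE009	GENE010
synthetic_pathway_B	synthetic: second chain segment	GENE011	GENE012	GENE013	GENE014	GENE015	GENE016	GENE017	GENE018	GENE019	GENE020
synthetic_pathway_C	synthetic: first coexpression block	GENE021	GENE022	GENE023	GENE024	GENE025	GENE026	GENE027	GENE028	GENE029	GENE030
synthetic_pathway_D	synthetic: scattered genes	GENE002	GENE009	GENE016	GENE023	GENE031	GENE038
synthetic_pathway_E	synthetic: second coexpression block	GENE031	GENE032	GENE033	GENE034	GENE035	GENE036	GENE037	GENE038	GENE039	GENE040
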