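protein	site	dataset_id	loc_prob	a_score
KINA	S100	DS001	0.764	NA
KINA	S100	DS002	0.967	NA
KINA	S100	DS007	0.956	NA
KINA	S100	DS009	0.792	NA
NEGP001	S101	DS004	0.867	NA
NULL001	S101	DS005	0.955	NA
NULL002	S102	DS008	0.893	NA
NULL003	S103	DS005	0.973	NA
NULL003	S103	DS006	0.933	NA
NULL003	S103	DS007	0.875	NA
NULL003	S103	DS009	0.819	NA
NULL003	S103	DS010	0.777	NA
NULL004	S104	DS004	0.757	NA
NULL005	S105	DS005	0.925	NA
NULL005	S105	DS007	0.814	NA
NULL006	S106	DS004	0.891	NA
NULL008	S108	DS002	0.779	NA
NULL008	S108	DS008	0.931	NA
NULL008	S108	DS010	0.792	NA
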