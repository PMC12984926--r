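protein	site	condition_code	pmid	fold_change	p_value	loc_prob	a_score
KINA	S100	COND0003	PMID0001	2.3456316446659433	0.036676397977862506	0.949	NA
KINA	S100	COND0008	PMID0003	2.5595724903524815	0.040861522220075136	0.942	NA
KINA	S100	COND0011	PMID0004	1.0798442909726873	0.008508124062791467	0.98	NA
KINA	S100	COND0014	PMID0005	0.5159574623266963	0.04723601627629251	0.966	NA
KINA	S100	COND0015	PMID0005	1.6161114901804823	0.014681192068383099	0.829	NA
KINA	S100	COND0018	PMID0006	0.5508160247234364	0.0074536026222631335	0.815	NA
KINA	S100	COND0019	PMID0007	0.6341967160811313	0.03596892956411466	0.936	NA
KINA	S100	COND0022	PMID0008	2.386627958611929	0.01620429762406275	0.937	NA
KINA	S100	COND0025	PMID0009	1.519811824657758	0.038940474926494065	0.979	NA
KINA	S100	COND0027	PMID0009	0.5159705079563895	0.01972205009078607	0.948	NA
KINA	S100	COND0029	PMID0010	1.4848734096560672	0.033929643395822495	0.783	NA
POSP001	S101	COND0003	PMID0001	1.7772224554400209	0.04148617575410754	0.835	NA
POSP001	S101	COND0004	PMID0002	4.188608920529121	0.029059887828771027	0.922	NA
POSP001	S101	COND0005	PMID0002	0.491460280776746	0.02350461876485497	0.879	NA
POSP001	S101	COND0006	PMID0002	1.4341393054041969	0.01825070600025356	0.879	NA
POSP001	S101	COND0007	PMID0003	0.423232886110862	0.014006231364328416	0.886	NA
POSP001	S101	COND0008	PMID0003	1.0531729212310166	0.029985792748630048	0.862	NA
POSP001	S101	COND0009	PMID0003	0.7990782269835472	0.04092848064610735	0.771	NA
POSP001	S101	COND0011	PMID0004	1.8078649575661878	0.0048916140221990645	0.983	NA
POSP001	S101	COND0014	PMID0005	0.31334838070058846	0.048184476303868	0.754	NA
POSP001	S101	COND0015	PMID0005	2.1913341650243576	0.008436822169460357	0.854	NA
POSP001	S101	COND0019	PMID0007	0.44095665763447733	0.004304170294199139	0.807	NA
POSP001	S101	COND0022	PMID0008	1.9047664105299054	0.043060534785036	0.775	NA
POSP001	S101	COND0025	PMID0009	1.7104621301555298	0.026239530101884158	0.871	NA
POSP001	S101	COND0027	PMID0009	0.272117065034385	0.032840543764177714	0.913	NA
POSP001	S101	COND0029	PMID0010	3.3576995540188412	0.4931609837803989	0.98	NA
NEGP001	S101	COND0003	PMID0001	0.5077101942721248	0.010812983894720674	0.834	NA
NEGP001	S101	COND0005	PMID0002	0.5647665188151204	0.012102905951905996	0.956	NA
NEGP001	S101	COND0008	PMID0003	0.37546865219470804	0.028245233651250604	0.805	NA
NEGP001	S101	COND0011	PMID0004	0.23864761703081266	0.035628404445014895	0.942	NA
NEGP001	S101	COND0014	PMID0005	2.6585090115107928	0.005404829897452146	0.89	NA
NEGP001	S101	COND0015	PMID0005	0.5502658052592768	0.025953793677035722	0.856	NA
NEGP001	S101	COND0018	PMID0006	1.870791146934855	0.04260951722972095	0.96	NA
NEGP001	S101	COND0019	PMID0007	0.3930548635314396	0.035731597105041146	0.822	NA
NEGP001	S101	COND0020	PMID0007	0.5844799438384138	0.01569908424280584	0.868	NA
NEGP001	S101	COND0022	PMID0008	0.3762573854959243	0.0057908571208827204	0.945	NA
NEGP001	S101	COND0023	PMID0008	0.4788134231959443	0.028750203375238925	0.771	NA
NEGP001	S101	COND0025	PMID0009	0.42307127823300916	0.04156859610229731	0.849	NA
NEGP001	S101	COND0027	PMID0009	2.0431352271819905	0.026016987895127387	0.774	NA
NEGP001	S101	COND0029	PMID0010	0.4717346174990777	0.03470055143116042	0.783	NA
NEGP001	S101	COND0030	PMID0010	2.4447925548353293	0.024995199474506083	0.805	NA
NULL001	S101	COND0010	PMID0004	2.340686683647774	0.0010598151129670441	0.975	NA
NULL001	S101	COND0011	PMID0004	2.9157462230753213	0.02976143803680316	0.798	NA
NULL001	S101	COND0015	PMID0005	0.5166665259521096	0.013812058058101685	0.883	NA
NULL001	S101	COND0018	PMID0006	2.134892498572294	0.019956345250830055	0.881	NA
NULL002	S102	COND0013	PMID0005	2.8936866035163953	0.04700823508901522	0.906	NA
NULL002	S102	COND0014	PMID0005	0.2985226344115002	0.03867466183146462	0.951	NA
NULL002	S102	COND0019	PMID0007	0.9697037532972173	0.004610549286007882	0.914	NA
NULL002	S102	COND0020	PMID0007	0.596533328541976	8.121714810840786e-4	0.92	NA
NULL002	S102	COND0023	PMID0008	0.2674343566102813	0.016675479349214584	0.853	NA
NULL002	S102	COND0025	PMID0009	0.22572969270045365	0.012092654616571963	0.916	NA
NULL002	S102	COND0028	PMID0010	1.7283098075144308	0.6384530642419123	0.757	NA
NULL003	S103	COND0002	PMID0001	1.6806804410494445	0.0016422110493294895	0.766	NA
NULL003	S103	COND0004	PMID0002	0.41076578526144003	0.03886486204573885	0.777	NA
NULL003	S103	COND0012	PMID0004	1.263418607818894	0.026307088788598776	0.955	NA
NULL003	S103	COND0017	PMID0006	0.2825214669225197	0.013306094182189554	0.948	NA
NULL003	S103	COND0019	PMID0007	0.59801412831002565	0.025246803963091227	0.764	NA
NULL003	S103	COND0025	PMID0009	3.1870535592072473	0.7574928312678821	0.977	NA
NULL003	S103	COND0029	PMID0010	1.433102796871112	0.004343511827755719	0.93	NA
NULL004	S104	COND0008	PMID0003	0.4502927872119812	0.041464874916709964	0.893	NA
NULL004	S104	COND0010	PMID0004	0.5215068110750756	0.032683054683730006	0.97	NA
NULL004	S104	COND0013	PMID0005	1.332645986116628	0.2667634559911676	0.899	NA
NULL004	S104	COND0017	PMID0006	1.5607151244819304	0.009307572734542191	0.98	NA
NULL004	S104	COND0026	PMID0009	2.639518832815677	0.4383352430537343	0.838	NA
NULL004	S104	COND0029	PMID0010	0.4585287797104933	0.03679601842304692	0.813	NA
NULL005	S105	COND0014	PMID0005	1.5267073182142694	0.04453512930776924	0.918	NA
NULL005	S105	COND0018	PMID0006	0.37112258035765916	0.40369963800767433	0.789	NA
NULL005	S105	COND0020	PMID0007	3.332538892728799	0.026051281881518663	0.851	NA
NULL005	S105	COND0022	PMID0008	0.6932126785259843	7.080706884153188e-4	0.816	NA
NULL005	S105	COND0025	PMID0009	0.48717505053711135	0.02634082967415452	0.837	NA
NULL006	S106	COND0001	PMID0001	0.2847999594597853	0.03858071004506201	0.792	NA
NULL006	S106	COND0003	PMID0001	1.9314766534801657	0.040719661372713746	0.793	NA
NULL006	S106	COND0006	PMID0002	0.2526951369397469	0.01665642694570124	0.907	NA
NULL006	S106	COND0027	PMID0009	1.5906547486093459	0.044562228303402666	0.934	NA
NULL007	S107	COND0017	PMID0006	2.545252588201135	0.009548972081393005	0.875	NA
NULL007	S107	COND0025	PMID0009	2.5777740023932516	0.04996530385687947	0.997	NA
NULL007	S107	COND0027	PMID0009	0.23098170096882573	9.317048359662295e-4	0.874	NA
NULL008	S108	COND0005	PMID0002	0.4198833908729264	0.03693523710826412	0.917	NA
NULL008	S108	COND0008	PMID0003	0.5083829096008239	0.021754971286281944	0.75	NA
NULL008	S108	COND0010	PMID0004	2.3166646962636026	0.0010233976179733872	0.841	NA
NULL008	S108	COND0017	PMID0006	1.5411859254823888	0.045008106133900584	0.883	NA
NULL008	S108	COND0023	PMID0008	0.38351150717813803	0.006251913716550917	0.889	NA
NULL008	S108	COND0024	PMID0008	1.9761763695555625	0.04984031252097339	0.886	NA
NULL008	S108	COND0027	PMID0009	2.7288279902594548	0.0032311426359228792	0.887	NA
NULL008	S108	COND0030	PMID0010	0.36920098771856585	0.04134421413764358	0.896	NA
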