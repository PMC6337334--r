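functional_group	gene_id	protein_id	product_name	localization
Hypothetical protein	CGI_10014580	EKC18206	Hypothetical protein CGI_10014580	Mit 0.58
Hypothetical protein	CGI_10010208	EKC18972	Hypothetical protein CGI_10010208	Ext 1
Hypothetical protein	CGI_10004853	EKC21005	Hypothetical protein CGI_10004853	Ext 0.42
Hypothetical protein	CGI_10002578	EKC22248	Hypothetical protein CGI_10002578	Ext 0.89
Hypothetical protein	CGI_10001746	EKC22673	Hypothetical protein CGI_10001746	Ext 0.90
Hypothetical protein	CGI_10013335	EKC23310	Hypothetical protein CGI_10013335	Nuc 0.50
Hypothetical protein	CGI_10013386	EKC24388	Hypothetical protein CGI_10013386	Ext 0.41
Hypothetical protein	CGI_10005578	EKC25384	Hypothetical protein CGI_10005578	Ext 0.43
Hypothetical protein	CGI_10013385	EKC24387	Hypothetical protein CGI_10013385	Ext 0.60
Hypothetical protein	CGI_10003237	EKC27225	Hypothetical protein CGI_10003237	Ext 0.99
Hypothetical protein	CGI_10025142	EKC28625	Hypothetical protein CGI_10025142	Ext 0.91
Hypothetical protein	CGI_10009961	EKC31321	Hypothetical protein CGI_10009961	Ext 0.99
Hypothetical protein	CGI_10025191	EKC32101	Hypothetical protein CGI_10025191	Cyt 0.38
Hypothetical protein	CGI_10012470	EKC33059	Hypothetical protein CGI_10012470	Ext 0.99
Hypothetical protein	CGI_10016093	EKC35263	Hypothetical protein CGI_10016093	Ext 0.52
Hypothetical protein	CGI_10016094	EKC35264	Hypothetical protein CGI_10016094	Ext 0.52
Hypothetical protein	CGI_10027526	EKC35968	Hypothetical protein CGI_10027526	ER 0.40
Hypothetical protein	CGI_10026725	EKC38958	Hypothetical protein CGI_10026725	Ext 0.62
Hypothetical protein	CGI_10022908	EKC41146	Hypothetical protein CGI_10022908	ER 0.25
Hypothetical protein	CGI_10008429	EKC41249	Hypothetical protein CGI_10008429	Ext 0.90
Hypothetical protein	CGI_10013282	EKC42653	Hypothetical protein CGI_10013282	Nuc 0.59
Enzyme	CGI_10009044	EKC19270	Putative tyrosinase-like protein tyr 1	Mem 0.82
Enzyme	CGI_10014286	EKC25254	Putative tyrosinase-like protein tyr-3	Mem 0.99
Enzyme	CGI_10006802	EKC29117	Tyrosinase-like protein 1	Ext 0.64
Enzyme	CGI_10016593	EKC32997	Peroxidase-like protein	Ext 0.49
Enzyme	CGI_10010889	EKC32754	Carbonic anhydrase 2	Cyt 0.41
Enzyme	CGI_10011324	EKC18733	Carbonic anhydrase 7	Ext 0.65
Enzyme	CGI_10003099	EKC28981	Cell surface hyaluronidase-like	Plast 0.39
Enzyme	CGI_10003100	EKC28982	Cell migration-inducing and hyaluronan-binding protein-like	Cyt 0.29
Enzyme	CGI_10007190	EKC19955	Metalloendopeptidase	Ext 0.39
Enzyme	CGI_10007191	EKC19956	Metalloendopeptidase	Ext 0.51
Enzyme	CGI_10020760	EKC31184	Zinc metalloproteinase nas-15	Ext 0.70
Protease inhibitor	CGI_10010154	EKC18991	Serine protease inhibitor dipetalogastin-like	Ext 0.55
Protease inhibitor	CGI_10010155	EKC18992	Serine protease inhibitor dipetalogastin-like	Ext 1
Structural protein	CGI_10005627	EKC20685	Hemicentin-1	Ext 0.72
Structural protein	CGI_10010553	EKC18864	IgGFc-binding protein (zonadhesin-like)	Ext 0.64
Structural protein	CGI_10010554	EKC18865	IgGFc-binding protein (zonadhesin-like)	Ext 0.72
Structural protein	CGI_10010555	EKC18866	IgGFc-binding protein (zonadhesin-like)	Ext 0.93
Structural protein	CGI_10010556	EKC18867	IgGFc-binding protein (zonadhesin-like)	Ext 0.60
Structural protein	CGI_10010557	EKC18868	IgGFc-binding protein (zonadhesin-like)	Ext 0.91
Structural protein	CGI_10023170	EKC34632	IgGFc-binding protein	Ext 0.52
Structural protein	CGI_10010465	EKC34579	Tenascin-X	Ext 0.80
Structural protein	CGI_10000981	EKC39076	Tenascin-R	Ext 0.84
Structural protein	CGI_10025295	EKC40994	Multiple EGF-like domains 10	Ext 0.42
Structural protein	CGI_10013281	EKC42652	Tenascin-R	Ext 0.99
Structural protein	CGI_10010827	EKC18813	Collagen-like protein 7	Ext 0.89
Structural protein	CGI_10010374	EKC27350	Collagen-like protein 7	Mem 0.56
Structural protein	CGI_10010375	EKC27351	Collagen-like protein 7	Mem 0.72
Structural protein	CGI_10011175	EKC27706	Collagen alpha-5(VI) chain	Ext 0.55
Calcification-related protein and calcium-binding protein	CGI_10010615	EKC18891	Aggrecan core protein	Ext 0.79
Calcification-related protein and calcium-binding protein	CGI_10006917	EKC42164	Asialoglycoprotein receptor 2	Ext 0.99
Calcification-related protein and calcium-binding protein	CGI_10006919	EKC42165	Perlucin-like protein	Ext 0.95
Calcification-related protein and calcium-binding protein	CGI_10006920	EKC42166	C-type mannose receptor 2	Ext 0.90
Calcification-related protein and calcium-binding protein	CGI_10006921	EKC42167	Perlucin-like protein	Ext 0.99
Calcification-related protein and calcium-binding protein	CGI_10006922	EKC42168	Perlucin-like protein	Ext 0.99
Calcification-related protein and calcium-binding protein	CGI_10008331	EKC19532	Protocadherin Fat 4-like	Lys 0.36
Calcification-related protein and calcium-binding protein	CGI_10018326	EKC34251	Protocadherin Fat 4	Cyt 0.72
Calcification-related protein and calcium-binding protein	CGI_10022907	EKC41145	Protocadherin Fat 4-like	Cyt 0.44
Calcification-related protein and calcium-binding protein	CGI_10006247	EKC20329	Putative calmodulin	Cyt 0.48
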