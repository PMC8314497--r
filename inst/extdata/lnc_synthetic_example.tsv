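gene_id	TCGA-SY-0001-01A-11R-A001-07	TCGA-SY-0002-01A-11R-A001-07	TCGA-SY-0003-01A-11R-A001-07	TCGA-SY-0004-01A-11R-A001-07	TCGA-SY-0005-01A-11R-A001-07	TCGA-SY-0006-01A-11R-A001-07	TCGA-SY-0007-01A-11R-A001-07	TCGA-SY-0008-01A-11R-A001-07	TCGA-SY-0009-01A-11R-A001-07	TCGA-SY-0010-01A-11R-A001-07	TCGA-SY-0011-01A-11R-A001-07	TCGA-SY-0012-01A-11R-A001-07	TCGA-SY-0013-01A-11R-A001-07	TCGA-SY-0014-01A-11R-A001-07	TCGA-SY-0015-01A-11R-A001-07	TCGA-SY-0016-01A-11R-A001-07	TCGA-SY-0017-01A-11R-A001-07	TCGA-SY-0018-01A-11R-A001-07	TCGA-SY-0019-01A-11R-A001-07	TCGA-SY-0020-01A-11R-A001-07	TCGA-SY-0021-01A-11R-A001-07	TCGA-SY-0022-01A-11R-A001-07	TCGA-SY-0023-01A-11R-A001-07	TCGA-SY-0024-01A-11R-A001-07	TCGA-SY-0025-01A-11R-A001-07	TCGA-SY-0026-01A-11R-A001-07	TCGA-SY-0027-01A-11R-A001-07	TCGA-SY-0028-01A-11R-A001-07	TCGA-SY-0029-01A-11R-A001-07	TCGA-SY-0030-01A-11R-A001-07
LNC_TARGET	10.476326975229425	2.7850418130855417	7.81058684116773	6.543589730759291	4.039778697513623	0.398529773605486	3.806055146334642	2.9445965136616965	7.655123714389191	4.760559805514268	5.028442408384856	3.821782987284899	5.861687392876117	5.840887361599323	0.3689963061271	19.35062925694207	11.264428860942045	8.302150866328375	3.579789119296854	11.90400303332522	5.370152832148374	6.1370032184636605	2.0482286408349757	21.097706881046438	7.271831559963527	29.024822972157843	25.555605635258107	7.32901469140455	11.512760173977352	25.457942806570692
LNC_DECOY1	16.568001255875597	9.043361209292671	21.780869676571598	34.54035482696874	5.102508096036271	5.265556406241855	5.676084570143249	12.171616866697741	1.2819884706620037	3.0312218070372774	6.02448180996351	8.916430921265892	19.74791878114584	2.7590723417260636	15.379384868107302	7.7525475643007304	7.415819227899421	7.942133532748686	9.203670924631425	12.871142788425752	4.063292119890268	18.298651961180624	8.1744657255300055	7.203688836319918	6.580708460153857	2.477877969139705	6.0043578277068645	4.043926941661792	2.391205550403449	10.070321107086935
LNC_DECOY2	14.832848282379752	7.151394867320585	35.69996547321731	6.292927985213502	4.848082517721862	2.504418796171558	3.285563119606059	4.0520500370628305	17.199028797645894	7.260191111352528	5.716690600663403	8.613014620497488	16.10455387478035	4.868125438341175	5.505378328399965	9.29107474230549	3.7473901665817584	6.455972245448234	21.860776600810034	1.4114261142340778	33.811964977631895	13.440459107589886	2.7999384730139063	15.815911935682994	2.8586417942370206	6.711463853053215	8.307417327491672	3.513945868588624	16.265308018231604	5.143458831951967
LNC_DECOY3	19.233446977560455	6.297151027156083	18.396856803768998	1.9157307814511824	5.297838387870841	17.067644911304413	0.698460055782735	21.727117845026022	33.25321922312772	8.482106186550954	10.911107818299644	6.603261385229544	2.6888692875569458	15.447844515178119	7.065579259221053	20.818954140245957	7.935415938381942	11.794604002310386	5.972564925323354	6.571412028700615	21.63514286957383	1.9228860089934492	16.82065185868538	9.857492820168627	20.691966983285656	5.795991836972253	7.516965332477248	2.1572074615833294	6.631489778610641	11.48520003157654
LNC_DECOY4	22.357022981665	5.976543131045742	12.492146754133268	0.7817813097408823	5.260543760602725	4.384329707592312	8.437793533527337	10.49863661752165	3.4955187630226474	5.560505003095539	10.59290191044044	8.312400802166605	12.99732473845242	8.270043746719473	0.2636036735545373	44.24417677441071	2.485058297828503	6.035753286439873	5.063571394857436	1.208584497978595	20.2877920001434	16.75966635876155	8.68450420505053	1.526355814589404	26.781182845287194	14.540750058349651	1.4767834598286949	5.28556083890915	6.834952864065392	18.506807220307948
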