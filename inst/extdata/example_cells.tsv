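# units: microns
sample_id	subject_id	x	y	CD3	CD8	FOXP3	compartment
core01	subj01	56.0559830628335	351.163306459785	0	0	0	tumor
core01	subj01	114.289322495461	151.574794854969	0	0	0	tumor
core01	subj01	222.147603984922	289.429725054651	0	0	0	tumor
core01	subj01	10.0524601526558	343.143177405	0	0	0	tumor
core01	subj01	186.492221988738	74.502201192081	0	0	0	tumor
core01	subj01	344.40427403897	253.079248871654	0	0	0	tumor
core01	subj01	101.000471506268	287.24632980302	1	1	0	tumor
core01	subj01	232.322534918785	216.722641605884	0	0	0	tumor
core01	subj01	2.3733027279377	81.8850393407047	0	0	0	tumor
core01	subj01	276.746375951916	359.995595458895	0	0	0	tumor
core01	subj01	92.4500187858939	49.4337316602468	0	0	0	tumor
core01	subj01	339.412984903902	380.618778523058	0	0	0	tumor
core01	subj01	61.534096300602	312.686050403863	0	0	0	tumor
core01	subj01	142.723725922406	384.854385908693	0	0	0	tumor
core01	subj01	218.081801664084	45.7007710821927	1	1	0	tumor
core01	subj01	0.479045510292053	391.020855680108	0	0	0	tumor
core01	subj01	127.129795961082	248.187800683081	1	1	0	tumor
core01	subj01	6.91574150696397	370.970906224102	0	0	0	tumor
core01	subj01	136.623210366815	80.894685164094	0	0	0	tumor
core01	subj01	137.37551998347	86.2116727046669	0	0	0	tumor
core01	subj01	93.0250773206353	368.770089093596	1	0	0	tumor
core01	subj01	24.5475310832262	288.846220355481	0	0	0	tumor
core01	subj01	164.950500708073	304.680555313826	0	0	0	tumor
core01	subj01	74.2048708721995	114.110980276018	0	0	0	tumor
core01	subj01	164.268825482577	137.463552318513	1	0	0	tumor
core01	subj01	56.0323422774673	136.557366605848	0	0	0	tumor
core01	subj01	2.17380672693253	315.183918736875	0	0	0	tumor
core01	subj01	240.695526264608	145.799996424466	0	0	0	tumor
core01	subj01	364.404050912708	266.049022041261	0	0	0	tumor
core01	subj01	70.1451135799289	149.12470402196	0	0	0	tumor
core01	subj01	292.47496528551	48.4083477407694	0	0	0	tumor
core01	subj01	6.46288385614753	332.338608056307	0	0	0	tumor
core01	subj01	234.446286503226	167.326912935823	1	0	0	tumor
core01	subj01	170.327371358871	32.8125341795385	0	0	0	tumor
core01	subj01	84.1963910497725	70.4110383056104	0	0	0	tumor
core01	subj01	190.880043338984	72.3844548687339	1	0	0	tumor
core01	subj01	301.92930996418	269.371021073312	0	0	0	tumor
core01	subj01	178.731711953878	242.798191960901	0	0	0	tumor
core01	subj01	148.480720818043	103.810522519052	1	0	0	tumor
core01	subj01	349.911361839622	236.145181395113	1	0	0	tumor
core01	subj01	173.838922940195	163.397286273539	1	0	0	tumor
core01	subj01	176.054710615426	346.571560110897	0	0	0	tumor
core01	subj01	32.7827333472669	43.2643620297313	0	0	0	tumor
core01	subj01	13.8477213680744	128.755974583328	0	0	0	tumor
core01	subj01	371.460792701691	67.3149310052395	1	0	0	tumor
core01	subj01	117.826518882066	20.6319665536284	0	0	0	tumor
core01	subj01	207.689714990556	221.312573179603	0	0	0	tumor
core01	subj01	94.5585699751973	56.7684628069401	0	0	0	tumor
core01	subj01	388.723923452199	63.5538298636675	1	0	0	tumor
core01	subj01	253.004600480199	311.52360541746	0	0	0	tumor
core01	subj01	383.30766633153	177.499623224139	0	0	0	tumor
core01	subj01	354.54159155488	52.608999889344	0	0	0	tumor
core01	subj01	209.273505490273	226.577903330326	0	0	0	tumor
core01	subj01	286.366253718734	309.552455041558	0	0	0	tumor
core01	subj01	296.257093176246	168.485622294247	0	0	0	tumor
core01	subj01	18.3585295453668	24.3322329595685	1	0	0	tumor
core01	subj01	383.117165509611	154.178573191166	0	0	0	tumor
core01	subj01	80.4546732455492	184.962046053261	0	0	0	tumor
core01	subj01	119.36567928642	16.5695325471461	0	0	0	tumor
core01	subj01	358.229067269713	164.290261268616	0	0	0	tumor
core01	subj01	226.430308818817	157.012409064919	0	0	0	tumor
core01	subj01	182.20319384709	256.942751351744	0	0	0	tumor
core01	subj01	159.787322115153	14.3743552267551	1	0	0	tumor
core01	subj01	33.2020121626556	37.2179065831006	0	0	0	tumor
core01	subj01	252.140284143388	350.196658819914	0	0	0	tumor
core01	subj01	186.037995945662	1.67919006198645	1	0	0	tumor
core01	subj01	228.951383661479	63.1413488648832	0	0	0	tumor
core01	subj01	264.892677310854	203.295155614614	0	0	0	tumor
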