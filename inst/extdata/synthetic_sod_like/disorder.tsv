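residue	predictor_1	predictor_2	predictor_3	predictor_4	predictor_5	predictor_6
1	0.177109343834227	0.287327220412047	0.0898998876851743	0.116202189253094	0.221980753582112	0.174121381356649
2	0.0836815312198109	0.1443352431683	0.123794291715938	0.148523157362559	0.104009276890357	0.0578737433259744
3	0.169518564660608	0.22231721567644	0.0150146106129453	0.0765891991817678	0.203774116956701	0.194396479920907
4	0.116215821028883	0.249701399475373	0.0337788206998837	0.144130130874154	0.115105848344124	0.165630835733331
5	0.10966965664898	0.221499986990645	0.0591895481298644	0.183242106679868	0.214568681403987	0.119270849383735
6	0.221981391706453	0.221502735730843	0.0247469314934549	0.137280602133573	0.167188405494524	0.109527274037702
7	0.168008980442747	0.208076280188495	0.105473983488538	0.152376096623043	0.092641107976655	0.0894855226232961
8	0.0960507980051735	0.206040862660398	0.0710143895695026	0.288952870178722	0.235921859508984	0.120895830078074
9	0.134396315842643	0.207283257429832	0	0.0801569498152413	0.0629255285942473	0.163650667957447
10	0.744253779341038	0.749075516554144	0.543964581290311	0.718510189349952	0.700305654172226	0.665450432609927
11	0.709967458096204	0.759714024899539	0.602322994896913	0.65908126024851	0.648549968111477	0.715837653273337
12	0.689663336028712	0.815052755259081	0.636452918274723	0.77740895715419	0.66871356824556	0.670609055122724
13	0.690926499786775	0.889741060758451	0.567070526552577	0.690021827676767	0.634349284038976	0.666553732242961
14	0.708047564269274	0.738667739517339	0.576440628965957	0.69449338756813	0.750554233108066	0.677362330716261
15	0.732861571969618	0.755436537968467	0.574296280149258	0.688026464914686	0.691421145841021	0.670474985399143
16	0.258124805432096	0.192239970665043	0	0.205741582384524	0.24481307451198	0.179527963879055
17	0.106177360807583	0.312964799468508	0.102734830210401	0.144489488948596	0.178292538390218	0.0182012426589616
18	0.327767201425922	0.16789357611043	0.0617043197171308	0.130130752233383	0.111609252423385	0.151850768836261
19	0.236077177074262	0.0843108078789075	0.0644491832227599	0.0766484273266404	0.141734258952978	0.165721897532819
20	0.178950700415204	0.230685002936307	0	0.125910947025855	0.0978443282630521	0.119115720342205
21	0.196877974678589	0.104459320808798	0	0.174390973078264	0.152803740750299	0.132949578980673
22	0.129686270930897	0.144620561861147	0.0841775404082786	0.122941861228257	0.238033164186757	0.108111925214664
23	0.143289267028078	0.293176606463771	0.0815220147432337	0.129277173019821	0.196060501960643	0.21938470598371
24	0.174453536798649	0.273072281226777	0.0111133221822837	0.230889412961271	0.108630821641409	0.0538059860894341
25	0.0632465348829229	0.24552121914319	0.0187504261530587	0.135581505906635	0.209858008780395	0.0489409181359245
26	0.149969334084814	0.103505363570784	0.0719981802104708	0.221429968738372	0.132364863287537	0.163348374730223
27	0.235558137122998	0.188165691204061	0.0644465383308328	0.142272972641723	0.151660553424337	0.065395270532901
28	0.25193774249245	0.128166453936739	0.108217562499805	0.179504850172413	0.17345262179811	0.120081586039107
29	0.185324912183287	0.266740967402721	0.126701655534848	0.188001377187625	0.11363374344107	0.121176086284887
30	0.172728995444202	0.181794479436707	0.0115447435144323	0.198683747808455	0.119122155165998	0.104923294027498
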