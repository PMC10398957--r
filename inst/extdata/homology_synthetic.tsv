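mouse	human
mvim	VIM
mchi3l1	CHI3L1
mupg001	UPG001
mupg002	UPG002
mupg003	UPG003
mupg004	UPG004
mupg005	UPG005
mupg006	UPG006
mupg007	UPG007
mupg008	UPG008
mupg009	UPG009
mupg010	UPG010
mupg011	UPG011
mupg012	UPG012
mupg013	UPG013
mupg014	UPG014
mupg015	UPG015
mupg016	UPG016
mupg017	UPG017
mupg018	UPG018
mnrxn1	NRXN1
mnrg3	NRG3
mgpc5	GPC5
merbb4	ERBB4
mg00702	G00702
mg01008	G01008
mg00907	G00907
mmalat1	MALAT1
mg00012	G00012
mg00238	G00238
mg00122	G00122
mg00440	G00440
mg00372	G00372
mg00242	G00242
mg00566	G00566
mg00364	G00364
mg00752	G00752
mg00905	G00905
mg00393	G00393
mg00363	G00363
mg00315	G00315
mg00564	G00564
mg01101	G01101
mg00436	G00436
mg01004	G01004
mg00472	G00472
mg00507	G00507
mg00858	G00858
mg00429	G00429
mg00086	G00086
mg00228	G00228
mg00190	G00190
mg00377	G00377
mg01007	G01007
mg00239	G00239
mg00825	G00825
mg00953	G00953
mg00106	G00106
mg00065	G00065
mg00453	G00453
mg00570	G00570
mg00751	G00751
mg00313	G00313
mg00516	G00516
mg00967	G00967
mg00663	G00663
mg01082	G01082
mg01143	G01143
mg00512	G00512
mg00921	G00921
mg00603	G00603
mg00977	G00977
mg00809	G00809
mg00728	G00728
mg00124	G00124
mg00803	G00803
mg00990	G00990
mg00376	G00376
mg00117	G00117
mg00428	G00428
mg00914	G00914
mg00375	G00375
mg00510	G00510
mg00166	G00166
mg00274	G00274
mg00187	G00187
mg00048	G00048
mg00132	G00132
mg00209	G00209
mg00044	G00044
mg00906	G00906
mg00731	G00731
mg00947	G00947
mg00145	G00145
mg00703	G00703
mg00171	G00171
mg00687	G00687
mg00021	G00021
mg00243	G00243
mg00785	G00785
mg01006	G01006
mg00288	G00288
mg00557	G00557
mg00757	G00757
mg01099	G01099
mg00640	G00640
mg00314	G00314
mg00501	G00501
mg01149	G01149
mg00373	G00373
mg00970	G00970
mg00408	G00408
mg01076	G01076
mg00159	G00159
mg00706	G00706
mg00112	G00112
mg00971	G00971
mg00795	G00795
mg00343	G00343
mg01134	G01134
mg00033	G00033
mg00289	G00289
mg00008	G00008
mg00474	G00474
mg01098	G01098
mg00659	G00659
mg00411	G00411
mg00674	G00674
mg00565	G00565
mg00484	G00484
mg00845	G00845
mg01119	G01119
mg00781	G00781
mg01095	G01095
mg00714	G00714
mg00259	G00259
mg00582	G00582
mg00819	G00819
mg00062	G00062
mg01059	G01059
mg00402	G00402
mg00875	G00875
mg00526	G00526
mg00330	G00330
mg00960	G00960
mg00713	G00713
mg00870	G00870
mg00167	G00167
mg00035	G00035
mg00082	G00082
mg00409	G00409
mg00599	G00599
mg00871	G00871
mg00888	G00888
mg00770	G00770
mg00534	G00534
mg00206	G00206
mg00240	G00240
mg00725	G00725
mg00002	G00002
mg00606	G00606
mg00009	G00009
mg01156	G01156
mg00300	G00300
mg00671	G00671
mg00014	G00014
mg00401	G00401
mg00901	G00901
mg00362	G00362
mg00233	G00233
mg00431	G00431
mg00113	G00113
mg01020	G01020
mg00320	G00320
mg00874	G00874
mg00207	G00207
mg00387	G00387
mg00984	G00984
mg00696	G00696
mg00804	G00804
mg00742	G00742
mg00536	G00536
mg00366	G00366
mg00331	G00331
mg00811	G00811
mg01063	G01063
mg01022	G01022
mg00398	G00398
mg00139	G00139
mg00316	G00316
mg00096	G00096
mg00748	G00748
mg00995	G00995
mg00623	G00623
mg00149	G00149
mg00495	G00495
mg00066	G00066
mg01080	G01080
mg00533	G00533
mg00873	G00873
mg00679	G00679
mg00733	G00733
mg00160	G00160
mg00749	G00749
mg00229	G00229
mg00291	G00291
mg00580	G00580
mg00023	G00023
mg00326	G00326
mg01111	G01111
mg00427	G00427
mg01130	G01130
mg00355	G00355
mg00673	G00673
mg00545	G00545
mg00157	G00157
mg00015	G00015
mg00497	G00497
mg00863	G00863
mg00272	G00272
mg01088	G01088
mg00085	G00085
mg00869	G00869
mg01146	G01146
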