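gene	direction
mvim	up
mchi3l1	up
mupg001	up
mupg002	up
mupg003	up
mupg004	up
mupg005	up
mupg006	up
mupg007	up
mupg008	up
mupg009	up
mupg010	up
mupg011	up
mupg012	up
mupg013	up
mupg014	up
mupg015	up
mupg016	up
mupg017	up
mupg018	up
mnrxn1	up
mnrg3	up
mgpc5	up
merbb4	up
mg00702	up
mg01008	up
mg00907	up
mmalat1	up
mg00012	up
mg00238	up
mg00122	up
mg00440	up
mg00372	up
mg00242	up
mg00566	up
mg00364	up
mg00752	up
mg00905	up
mg00393	up
mg00363	up
mg00315	up
mg00564	up
mg01101	up
mg00436	up
mg01004	up
mg00472	up
mg00507	up
mg00858	up
mg00429	up
mg00086	up
mg00228	up
mg00190	up
mg00377	up
mg01007	up
mg00239	up
mg00825	up
mg00953	up
mg00106	up
mg00065	up
mg00453	up
mg00570	up
mg00751	up
mg00313	up
mg00516	up
mg00967	up
mg00663	up
mg01082	up
mg01143	up
mg00512	up
mg00921	up
mg00603	up
mg00977	up
mg00809	up
mg00728	up
mg00124	up
mg00803	up
mg00990	up
mg00376	up
mg00117	up
mg00428	up
mg00914	up
mg00375	up
mg00510	up
mg00166	up
mg00274	up
mg00187	up
mg00048	up
mg00132	up
mg00209	up
mg00044	up
mg00906	up
mg00731	up
mg00947	up
mg00145	up
mg00703	up
mg00171	up
mg00687	up
mg00021	up
mg00243	up
mg00785	up
mg01006	up
mg00288	up
mg00557	up
mg00757	up
mg01099	up
mg00640	up
mg00314	up
mg00501	up
mg01149	up
mg00373	up
mg00970	up
mg00408	up
mg01076	up
mg00159	up
mg00706	up
mg00112	up
mg00971	up
mg00795	up
mg00343	up
mg01134	up
mg00033	up
mg00289	up
mg00008	up
mg00474	up
mg01098	up
mg00659	up
mg00411	up
mg00674	up
mg00565	up
mg00484	up
mg00845	up
mg01119	up
mg00781	up
mg01095	up
mg00714	up
mg00259	up
mg00582	up
mg00819	up
mg00062	up
mg01059	up
mg00402	up
mg00875	up
mg00526	up
mg00330	up
mg00960	up
mg00713	up
mg00870	up
mg00167	up
mg00035	up
mg00082	up
mg00409	up
mg00599	up
mg00871	up
mg00888	up
mg00770	up
mg00534	up
mg00206	up
mg00240	up
mg00725	up
mg00002	up
mg00606	up
mg00009	up
mg01156	up
mg00300	up
mg00671	up
mg00014	up
mg00401	up
mg00901	up
mg00362	up
mg00233	up
mg00431	up
mg00113	up
mg01020	up
mg00320	up
mg00874	up
mg00207	up
mg00387	up
mg00984	up
mg00696	up
mg00804	up
mg00742	up
mg00536	up
mg00366	up
mg00331	up
mg00811	up
mg01063	up
mg01022	up
mg00398	up
mg00139	up
mg00316	up
mg00096	up
mg00748	up
mg00995	up
mg00623	up
mg00149	up
mg00495	up
mg00066	up
mg01080	up
mg00533	up
mg00873	up
mg00679	up
mg00733	up
mg00160	up
mg00749	up
mg00229	up
mg00291	up
mg00580	up
mg00023	up
mg00326	up
mg01111	up
mg00427	down
mg01130	down
mg00355	down
mg00673	down
mg00545	down
mg00157	down
mg00015	down
mg00497	down
mg00863	down
mg00272	down
mg01088	down
mg00085	down
mg00869	down
mg01146	down
morph01	up
morph02	up
morph03	up
morph04	up
morph05	up
morph06	up
morph07	up
morph08	up
morph09	up
morph10	up
morph11	up
morph12	up
morph13	up
morph14	up
morph15	up
morph16	up
morph17	up
morph18	up
morph19	up
morph20	up
morph21	up
morph22	up
morph23	up
morph24	up
morph25	up
morph26	up
morph27	up
morph28	up
morph29	up
morph30	down
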