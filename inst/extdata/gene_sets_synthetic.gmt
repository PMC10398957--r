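homeostatic_program	synthetic	NRXN1	NRG3	GPC5	ERBB4	NFIA	DNG001	DNG002	DNG003	DNG004	DNG005	DNG006	DNG007	DNG008	DNG009	DNG010	DNG011	DNG012	DNG013	DNG014	DNG015	DNG016	DNG017	DNG018	DNG019	DNG020	DNG021	DNG022	DNG023	DNG024	DNG025
reactivity_program	synthetic	VIM	CHI3L1	UPG001	UPG002	UPG003	UPG004	UPG005	UPG006	UPG007	UPG008	UPG009	UPG010	UPG011	UPG012	UPG013	UPG014	UPG015	UPG016	UPG017	UPG018	UPG019	UPG020	UPG021	UPG022	UPG023
random_set_a	synthetic	G00266	G00181	G00464	G00261	G00690	G00671	G01060	G00116	G00567	G00301	G00566	G00101	G00753	G00184	G00136	G00806	G00835	G00919	G00191	G00076	G00608	G00203	G01008	G00307	G00170	G00585	G00417	G00161	G01045	G00431	G00809	G00341	G01086	G00781	G00168	G00297	G00044	G00799	G01161	G00069
random_set_b	synthetic	G00612	G00716	G00341	G00217	G00478	G00599	G00988	G00608	G00278	G00667	G01110	G00395	G00048	G00476	G01015	G01107	G00837	G00810	G00066	G01098	G00373	G00907	G00244	G00231	G00131
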