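# Grantham chemical distance, recomputed from grantham_properties.tsv (see build_grantham_matrix)
	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	0	195.003744	125.74859	106.712551	112.58149	59.995357	85.493736	93.662433	105.570901	96.187072	84.439582	110.418026	26.874338	90.76117	111.264592	99.132497	58.023328	64.430251	147.726579	111.588214
C	195.003744	0	153.574357	169.437459	204.388487	158.231773	173.842682	197.249796	201.579336	197.428971	195.554332	138.766468	168.590621	154.230843	179.534838	111.672496	148.929455	191.232501	214.362373	193.724701
D	125.74859	153.574357	0	44.604636	176.526193	93.767551	81.23798	168.080962	101.456899	171.757202	160.026734	23.005355	107.909663	61.284474	95.813528	65.470815	85.076137	152.013397	190.552307	159.937407
E	106.712551	169.437459	44.604636	0	140.212063	97.8519	40.794154	134.162145	56.867955	138.343067	126.084923	40.858952	93.730854	29.273706	54.018845	79.787569	65.501313	121.328506	152.259465	122.776865
F	112.58149	204.388487	176.526193	140.212063	0	153.125519	99.995055	21.277014	102.141346	21.823921	28.527844	158.112189	113.727154	115.586936	97.032721	154.807902	102.858719	49.93519	39.655062	21.609665
G	59.995357	158.231773	93.767551	97.8519	153.125519	0	97.533402	135.41881	126.457976	137.691643	126.944873	79.345856	41.6291	87.166387	125.129193	55.267363	59.156452	108.787388	183.790213	146.926293
H	85.493736	173.842682	81.23798	40.794154	99.995055	97.533402	0	94.337529	32.402887	98.693015	86.343929	68.354856	76.277123	24.083989	28.819222	88.935528	46.75287	83.892947	114.561087	83.328445
I	93.662433	197.249796	168.080962	134.162145	21.277014	135.41881	94.337529	0	101.612333	4.855121	10.120986	148.914096	95.376088	108.566243	97.586564	141.79796	89.282902	29.609071	60.527837	33.047699
K	105.570901	201.579336	101.456899	56.867955	102.141346	126.457976	32.402887	101.612333	0	106.335513	94.490097	93.882683	102.713994	53.22834	26.003946	120.53258	77.741056	96.997399	109.434529	84.786445
L	96.187072	197.428971	171.757202	138.343067	21.823921	137.691643	98.693015	4.855121	106.335513	0	14.303167	152.33098	97.776198	112.441477	101.880293	144.079235	92.354275	31.78479	60.980496	35.677312
M	84.439582	195.554332	160.026734	126.084923	28.527844	126.944873	86.343929	10.120986	94.490097	14.303167	0	141.152647	86.594799	100.899143	91.638277	134.863884	81.039693	21.521799	66.636871	35.222695
N	110.418026	138.766468	23.005355	40.858952	158.112189	79.345856	68.354856	148.914096	93.882683	152.33098	141.152647	0	90.157397	45.752197	85.113938	46.239775	64.774288	132.877723	173.781736	142.22937
P	26.874338	168.590621	107.909663	93.730854	113.727154	41.6291	76.277123	95.376088	102.713994	97.776198	86.594799	90.157397	0	75.135878	102.714871	73.352569	37.563625	67.786598	146.620818	109.615572
Q	90.76117	154.230843	61.284474	29.273706	115.586936	87.166387	24.083989	108.566243	53.22834	112.441477	100.899143	45.752197	75.135878	0	42.813932	68.197874	41.104763	96.325719	130.204408	98.783252
R	111.264592	179.534838	95.813528	54.018845	97.032721	125.129193	28.819222	97.586564	26.003946	101.880293	91.638277	85.113938	102.714871	42.813932	0	109.213153	70.971026	95.797076	101.290481	77.107644
S	99.132497	111.672496	65.470815	79.787569	154.807902	55.267363	88.935528	141.79796	120.53258	144.079235	134.863884	46.239775	73.352569	68.197874	109.213153	0	57.749028	123.033958	176.577562	143.107384
T	58.023328	148.929455	85.076137	65.501313	102.858719	59.156452	46.75287	89.282902	77.741056	92.354275	81.039693	64.774288	37.563625	41.104763	70.971026	57.749028	0	69.496217	128.315879	92.247642
V	64.430251	191.232501	152.013397	121.328506	49.93519	108.787388	83.892947	29.609071	96.997399	31.78479	21.521799	132.877723	67.786598	96.325719	95.797076	123.033958	69.496217	0	87.963564	54.662782
W	147.726579	214.362373	190.552307	152.259465	39.655062	183.790213	114.561087	60.527837	109.434529	60.980496	66.636871	173.781736	146.620818	130.204408	101.290481	176.577562	128.315879	87.963564	0	37.11377
Y	111.588214	193.724701	159.937407	122.776865	21.609665	146.926293	83.328445	33.047699	84.786445	35.677312	35.222695	142.22937	109.615572	98.783252	77.107644	143.107384	92.247642	54.662782	37.11377	0
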