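# SYNTHETIC physicochemical distance matrix in the Schneider-Wrede style; see build_sw_matrix
	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	0	0.207955	0.493865	0.487376	0.410812	0.182766	0.424564	0.386291	0.527528	0.380761	0.307823	0.430469	0.218288	0.423926	0.544032	0.184332	0.194286	0.286124	0.545861	0.4355
C	0.207955	0	0.658741	0.626452	0.267753	0.359394	0.525146	0.233238	0.623237	0.215095	0.177666	0.580695	0.32708	0.534713	0.620938	0.347405	0.302314	0.150856	0.453531	0.374608
D	0.493865	0.658741	0	0.111988	0.738342	0.389773	0.236217	0.781861	0.256591	0.769068	0.649483	0.100028	0.383919	0.207941	0.307301	0.330375	0.362226	0.714743	0.694333	0.578971
E	0.487376	0.626452	0.111988	0	0.669432	0.413966	0.143983	0.727224	0.145702	0.711955	0.589146	0.105842	0.373197	0.128486	0.201662	0.331529	0.328025	0.672385	0.60014	0.492481
F	0.410812	0.267753	0.738342	0.669432	0	0.560712	0.548649	0.131011	0.613024	0.099214	0.115397	0.663677	0.48768	0.576583	0.60231	0.504126	0.411574	0.195174	0.271661	0.272853
G	0.182766	0.359394	0.389773	0.413966	0.560712	0	0.38157	0.558193	0.487971	0.545349	0.448828	0.327819	0.146314	0.362415	0.505568	0.104467	0.203446	0.462947	0.632618	0.504565
H	0.424564	0.525146	0.236217	0.143983	0.548649	0.38157	0	0.619724	0.111599	0.598349	0.469291	0.163737	0.296636	0.043213	0.127969	0.2828	0.238375	0.574414	0.462853	0.351568
I	0.386291	0.233238	0.781861	0.727224	0.131011	0.558193	0.619724	0	0.692951	0.049736	0.171812	0.71248	0.516344	0.643557	0.691423	0.521036	0.447087	0.107578	0.402254	0.38857
K	0.527528	0.623237	0.256591	0.145702	0.613024	0.487971	0.111599	0.692951	0	0.672945	0.547818	0.220349	0.408075	0.133141	0.070935	0.390408	0.34552	0.657867	0.494952	0.404249
L	0.380761	0.215095	0.769068	0.711955	0.099214	0.545349	0.598349	0.049736	0.672945	0	0.136154	0.695356	0.492418	0.621856	0.666966	0.505579	0.427512	0.120217	0.365761	0.350846
M	0.307823	0.177666	0.649483	0.589146	0.115397	0.448828	0.469291	0.171812	0.547818	0.136154	0	0.57057	0.374314	0.491768	0.538451	0.394879	0.306081	0.165057	0.288476	0.234299
N	0.430469	0.580695	0.100028	0.105842	0.663677	0.327819	0.163737	0.71248	0.220349	0.695356	0.57057	0	0.295466	0.127276	0.255987	0.257193	0.279798	0.646861	0.615178	0.49453
P	0.218288	0.32708	0.383919	0.373197	0.48768	0.146314	0.296636	0.516344	0.408075	0.492418	0.374314	0.295466	0	0.28205	0.407957	0.099763	0.121944	0.438795	0.512183	0.380612
Q	0.423926	0.534713	0.207941	0.128486	0.576583	0.362415	0.043213	0.643557	0.133141	0.621856	0.491768	0.127276	0.28205	0	0.149313	0.268626	0.239768	0.592881	0.496304	0.380715
R	0.544032	0.620938	0.307301	0.201662	0.60231	0.505568	0.127969	0.691423	0.070935	0.666966	0.538451	0.255987	0.407957	0.149313	0	0.407537	0.35384	0.661898	0.459095	0.371214
S	0.184332	0.347405	0.330375	0.331529	0.504126	0.104467	0.2828	0.521036	0.390408	0.505579	0.394879	0.257193	0.099763	0.268626	0.407537	0	0.109187	0.436493	0.548653	0.419557
T	0.194286	0.302314	0.362226	0.328025	0.411574	0.203446	0.238375	0.447087	0.34552	0.427512	0.306081	0.279798	0.121944	0.239768	0.35384	0.109187	0	0.377049	0.440673	0.313011
V	0.286124	0.150856	0.714743	0.672385	0.195174	0.462947	0.574414	0.107578	0.657867	0.120217	0.165057	0.646861	0.438795	0.592881	0.661898	0.436493	0.377049	0	0.443515	0.396562
W	0.545861	0.453531	0.694333	0.60014	0.271661	0.632618	0.462853	0.402254	0.494952	0.365761	0.288476	0.615178	0.512183	0.496304	0.459095	0.548653	0.440673	0.443515	0	0.133141
Y	0.4355	0.374608	0.578971	0.492481	0.272853	0.504565	0.351568	0.38857	0.404249	0.350846	0.234299	0.49453	0.380612	0.380715	0.371214	0.419557	0.313011	0.396562	0.133141	0
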