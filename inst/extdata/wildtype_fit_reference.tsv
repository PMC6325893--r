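strain	carbon_source	ad_lognormal	ad_weibull	ad_gamma	ks_lognormal	ks_weibull	ks_gamma	cvm_lognormal	cvm_weibull	cvm_gamma	gamma_shape	gamma_rate
BY4743	Dextrose(2%)	3.161116	2.479761	0.769909	0.03981673	0.0200254	0.03695591	0.47005958	0.09900603	0.3672601	6.624628	0.060432
BY4743	Dextrose(2%)	2.481744	3.453834	0.907658	0.03451547	0.02340116	0.04168316	0.35931106	0.11427787	0.50807483	6.839326	0.0613
BY4743	Dextrose(2%)	2.350162	4.639409	1.397938	0.03299974	0.02592211	0.04547749	0.29286774	0.15548112	0.67758731	7.939692	0.062422
BY4743	Dextrose(2%)	9.379353	3.256118	2.080058	0.05563504	0.02812955	0.03526128	1.17880153	0.17324015	0.43802261	6.327387	0.051845
BY4743	Dextrose(0.5%)	2.400366	5.534772	1.885079	0.08902688	0.04867087	0.02641991	3.3903958	0.89513746	0.14380645	6.631854	0.056427
BY4743	Dextrose(0.5%)	2.681816	4.711678	1.737208	0.08033942	0.04140794	0.02836311	2.18084296	0.45362558	0.25145377	7.028829	0.059809
BY4743	Dextrose(0.5%)	2.554072	4.049485	1.352729	0.03971196	0.01749115	0.04803978	0.42735647	0.05621092	0.67291786	6.523879	0.056879
BY4743	Dextrose(0.5%)	2.238338	4.465921	1.296817	0.02285933	0.02726508	0.05816792	0.13284149	0.12489905	0.85713441	6.682971	0.05811
BY4743	Dextrose(0.5%)	1.657507	5.112165	1.088213	0.03371034	0.02031434	0.05064857	0.29001527	0.07296596	0.7676489	6.92371	0.059789
BY4743	Dextrose(0.5%)	2.257491	4.7403	1.40862	0.03967463	0.02448684	0.0559948	0.25676227	0.09533312	0.8832544	7.118115	0.060818
BY4743	Dextrose(0.1%)	2.093822	3.809769	0.68981	0.04676217	0.01914837	0.05218087	0.37783319	0.05085369	0.52856064	5.491663	0.051904
BY4743	Dextrose(0.1%)	3.495197	2.657985	1.090478	0.03157352	0.02077244	0.04550404	0.24346903	0.07980251	0.63674229	5.502986	0.050511
BY4743	Dextrose(0.1%)	0.998583	5.800609	0.817631	0.03476032	0.02287527	0.0470058	0.31940454	0.08175868	0.5341655	5.038751	0.050269
BY4743	Dextrose(0.1%)	1.429023	4.734133	0.725159	0.0423421	0.02390521	0.0375983	0.5340163	0.14950146	0.3783479	4.987775	0.049489
BY4743	Dextrose(0.05%)	3.090379	4.551848	0.58666	0.02497927	0.02174877	0.05687372	0.12924293	0.10453503	0.8573444	4.084743	0.043347
BY4743	Dextrose(0.05%)	1.194635	5.519737	0.903827	0.03355771	0.02326251	0.04499282	0.21631169	0.0932074	0.65946712	4.601468	0.047501
BY4743	Dextrose(0.05%)	2.240336	5.114651	0.608227	0.03175526	0.03285626	0.05452121	0.29699836	0.22149283	0.81935031	4.13688	0.046411
BY4743	Dextrose(0.05%)	1.685737	5.903186	0.693725	0.03123157	0.02902691	0.04582818	0.36362006	0.21041353	0.66669872	4.137698	0.046938
BY4743	Dextrose(0.05%)	2.300439	3.695214	0.388641	0.03437376	0.02568932	0.04441959	0.36181641	0.17975946	0.58983905	4.936219	0.052235
BY4743	Dextrose(0.05%)	1.850587	4.21797	0.692334	0.03038782	0.02735584	0.04853824	0.29098868	0.163558	0.6771316	4.86957	0.04992
BY4743	Galactose(2%)	4.48614	2.026274	1.063566	0.02452582	0.02348538	0.05047681	0.21260335	0.13107877	0.75881009	4.352128	0.049247
BY4743	Galactose(2%)	4.019618	1.957646	0.849565	0.02877741	0.02730421	0.04607656	0.30208734	0.17412821	0.69220803	4.34835	0.048053
BY4743	Galactose(2%)	2.866003	3.179497	0.85723	0.05826168	0.02860853	0.02928325	0.82117011	0.20351277	0.21822962	4.460477	0.050979
BY4743	Galactose(2%)	3.541828	2.324092	0.906612	0.04896814	0.0244765	0.02815314	0.68864672	0.142866	0.23356047	4.651173	0.053049
BY4743	Galactose(2%)	5.23192	1.70193	1.398188	0.04622281	0.03137464	0.03432644	0.51534675	0.14159861	0.37807561	4.561268	0.0503
BY4743	Galactose(2%)	4.898133	2.389382	1.858014	0.04906314	0.02468138	0.03192201	0.6025577	0.14846111	0.28277728	4.886206	0.053239
BY4743	Glycerol(2%)	4.023934	1.706263	0.484643	0.06243632	0.0343775	0.02854547	0.94857643	0.2648869	0.18764683	4.576071	0.046215
BY4743	Glycerol(2%)	4.912524	1.426551	0.417717	0.06189211	0.03498619	0.03483287	0.87430393	0.32292365	0.27798862	4.19207	0.046484
BY4743	Glycerol(2%)	3.537731	2.212626	0.166045	0.04390741	0.01948744	0.03145215	0.62067725	0.06717106	0.23822465	4.243508	0.04657
BY4741	Dextrose(2%)	8.884836	1.728113	1.143929	0.05150172	0.01837113	0.02720123	0.75401418	0.05740949	0.20737051	3.651767	0.074363
BY4741	Dextrose(2%)	9.115701	3.162732	1.503567	0.04546417	0.01249397	0.03272571	0.56067769	0.02099474	0.30962955	4.003634	0.083534
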