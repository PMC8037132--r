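peptide	clust_index	rel_pop	U_repr	U_EP	U_dse	U_dsh	spread	plain	identity_consistent
H1	A1	70.8	-52.815	-50.607	8.886	-11.094	1.203	FALSE	TRUE
H1	A2	12.0	-51.375	-51.288	9.046	-9.132	1.172	TRUE	TRUE
H1	A3	7.0	-50.788	-50.638	9.936	-10.085	0.571	TRUE	TRUE
H1	A4	8.4	-51.005	-51.168	9.391	-9.227	0.343	TRUE	TRUE
H1	A5	1.8	-51.006	-49.864	9.771	-10.913	0.495	TRUE	TRUE
H1	B1	63.5	-50.890	-47.567	8.618	-11.841	0.342	FALSE	FALSE
H1	B2	18.9	-50.631	-45.628	7.283	-12.287	0.500	TRUE	TRUE
H1	B3	11.4	-50.676	-45.877	6.823	-11.622	0.464	TRUE	TRUE
H1	B4	3.8	-50.268	-47.143	8.347	-11.472	0.254	TRUE	TRUE
H1	B5	2.4	-50.361	-48.345	8.667	-10.683	0.273	TRUE	TRUE
H1	C1	37.3	-51.075	-50.940	10.970	-11.105	0.626	FALSE	TRUE
H1	C2	21.7	-51.325	-49.756	9.965	-11.534	0.518	TRUE	TRUE
H1	C3	33.9	-50.266	-49.160	10.833	-11.940	0.601	TRUE	TRUE
H1	C4	5.6	-50.346	-50.611	10.391	-10.126	0.387	TRUE	TRUE
H1	C5	1.5	-50.230	-50.292	10.715	-9.654	0.001	TRUE	FALSE
H3	D1	78.5	-55.104	-51.538	9.048	-12.613	1.271	FALSE	TRUE
H3	D2	10.7	-53.506	-52.317	10.716	-11.905	0.821	TRUE	TRUE
H3	D3	3.6	-53.496	-52.045	9.897	-11.347	0.369	TRUE	TRUE
H3	D4	3.7	-53.642	-50.904	10.819	-13.557	0.292	TRUE	TRUE
H3	D5	3.5	-53.541	-49.327	9.270	-13.484	0.267	TRUE	TRUE
H3	E1	44.4	-54.087	-52.973	10.398	-11.511	2.127	FALSE	TRUE
H3	E2	26.2	-54.218	-53.461	9.214	-9.971	1.573	TRUE	TRUE
H3	E3	15.8	-53.681	-54.362	10.045	-9.364	4.559	TRUE	TRUE
H3	E4	10.8	-54.442	-51.790	8.913	-11.565	0.578	TRUE	TRUE
H3	E5	2.8	-53.662	-53.151	9.899	-10.410	1.772	TRUE	TRUE
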