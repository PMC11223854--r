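residue	n_carbon	n_hydrogen	n_nitrogen	n_oxygen	n_sulfur	hydropathy_kd	hydrophilicity_hw	hydrophobicity_eisenberg	hydrophobicity_zimmerman	hydrophobicity_jones	surrounding_hydrophobicity	transfer_energy_nozaki	hydration_potential	molecular_weight	residue_volume	volume_grantham	size_dawson	vdw_volume_normalized	asa_tripeptide	asa_folded	percent_buried	mean_buried_area	polarity_grantham	polarity_zimmerman	isoelectric_point	net_charge	h_bond_donors	polarizability	refractivity	helix_propensity_cf	sheet_propensity_cf	turn_propensity_cf	flexibility_bhaskaran	hydrophobic_param_levitt	steric_parameter	ave_nonbonded_energy
A	3	7	1	2	0	1.8	-0.5	0.25	0.83	0.87	12.28	0.5	1.94	89.09	52.6	31	2.5	1	115	27.8	51	86.6	8.1	0	6	0	0	0.046	4.34	1.42	0.83	0.74	0.357	-0.5	0.52	-1.895
R	6	14	4	2	0	-4.5	3	-1.76	0.83	0.85	11.49	0	-19.92	174.2	109.1	124	7.5	6.13	225	94.7	5	162.2	10.5	52	10.76	1	4	0.291	26.66	0.98	0.93	1.01	0.529	3	0.68	-1.475
N	4	8	2	3	0	-3.5	0.2	-0.64	0.09	0.09	11	0	-9.68	132.12	75.7	56	5	2.95	160	60.1	22	103.3	11.6	3.38	5.41	0	2	0.134	13.28	0.67	0.89	1.46	0.463	0.2	0.76	-1.56
D	4	7	1	4	0	-3.5	3	-0.72	0.64	0.66	10.97	0	-10.95	133.1	68.4	54	2.5	2.78	150	60.6	19	97.8	13	49.7	2.77	-1	1	0.105	12	1.01	0.54	1.52	0.511	2.5	0.76	-1.518
C	3	7	1	2	1	2.5	-1	0.04	1.48	1.52	14.93	0	-1.24	121.15	68.3	55	3	2.43	135	15.5	74	132.3	5.5	1.48	5.05	0	0	0.128	35.77	0.7	1.19	0.96	0.346	-1	0.62	-2.035
Q	5	10	2	3	0	-3.5	0.2	-0.69	0	0	11.28	0	-9.38	146.15	89.7	85	6	3.95	180	68.7	16	119.2	10.5	3.53	5.65	0	2	0.18	17.56	1.11	1.1	0.96	0.493	0.2	0.68	-1.521
E	5	9	1	4	0	-3.5	3	-0.62	0.65	0.67	11.19	0	-10.2	147.13	84.7	83	5	3.78	190	68.2	16	113.9	12.3	49.9	3.22	-1	1	0.151	17.26	1.51	0.37	0.95	0.497	2.5	0.68	-1.535
G	2	5	1	2	0	-0.4	0	0.16	0.1	0.1	12.01	0	2.39	75.07	36.3	3	0.5	0	75	24.5	52	62.9	9	0	5.97	0	0	0	0	0.57	0.75	1.56	0.544	0	0	-1.898
H	6	9	3	2	0	-3.2	-0.5	-0.4	1.1	0.87	12.84	0.5	-10.27	155.16	91.9	96	6	4.66	195	50.7	34	155.8	10.4	51.6	7.59	0	1	0.23	21.81	1	0.87	0.95	0.323	-0.5	0.7	-1.755
I	6	13	1	2	0	4.5	-1.8	0.73	3.07	3.15	14.77	1.8	2.15	131.17	102	111	5.5	4	175	22.8	66	158	5.2	0.13	6.02	0	0	0.186	19.06	1.08	1.6	0.47	0.462	-1.8	1.02	-1.951
L	6	13	1	2	0	3.8	-1.8	0.53	2.52	2.17	14.1	1.8	2.28	131.17	102	111	5.5	4	170	27.6	60	164.1	4.9	0.13	5.98	0	0	0.186	18.78	1.21	1.3	0.5	0.365	-1.8	0.98	-1.966
K	6	14	2	2	0	-3.9	3	-1.1	1.6	1.64	10.8	0	-9.52	146.19	105.1	119	7	4.77	200	103	3	115.5	11.3	49.5	9.74	1	2	0.219	21.29	1.16	0.74	1.19	0.466	3	0.68	-1.374
M	5	11	1	2	1	1.9	-1.3	0.26	1.4	1.67	14.33	1.3	-1.48	149.21	97.7	105	6	4.43	185	33.5	52	172.9	5.7	1.43	5.74	0	0	0.221	21.64	1.45	1.05	0.6	0.295	-1.3	0.78	-1.963
F	9	11	1	2	0	2.8	-2.5	0.61	2.75	2.87	13.43	2.5	-0.76	165.19	113.9	132	6.5	5.89	210	25.5	58	194.1	5.2	0.35	5.48	0	0	0.29	29.4	1.13	1.38	0.66	0.314	-2.5	0.7	-1.864
P	5	9	1	2	0	-1.6	0	-0.07	2.7	2.77	11.19	0	-3.68	115.13	73.6	32.5	5.5	2.72	145	51.5	25	92.9	8	1.58	6.3	0	0	0.131	10.93	0.57	0.55	1.56	0.509	-1.4	0.36	-1.699
S	3	7	1	3	0	-0.8	0.3	-0.26	0.14	0.07	11.26	0	-5.06	105.09	54.9	32	3	1.6	115	42	35	85.6	9.2	1.67	5.68	0	1	0.062	6.35	0.77	0.75	1.43	0.507	0.3	0.53	-1.753
T	4	9	1	3	0	-0.7	-0.4	-0.18	0.54	0.07	11.65	0.4	-4.88	119.12	71.2	61	5	2.6	140	45	30	106.5	8.6	1.66	5.66	0	1	0.108	11.01	0.83	1.19	0.98	0.444	-0.4	0.5	-1.767
W	11	12	2	2	0	-0.9	-3.4	0.37	0.31	3.77	12.95	3.4	-5.88	204.24	135.4	170	7	8.08	255	34.7	49	224.6	5.4	2.1	5.89	0	1	0.409	42.53	1.08	1.37	0.6	0.305	-3.4	0.7	-1.869
Y	9	11	1	3	0	-1.3	-2.3	0.02	2.97	2.67	13.29	2.3	-6.11	181.19	116.2	136	7	6.47	230	55.2	24	177.7	6.2	1.61	5.66	0	1	0.298	31.53	0.69	1.47	1.14	0.42	-2.3	0.7	-1.686
V	5	11	1	2	0	4.2	-1.5	0.54	1.79	1.87	15.07	1.5	1.99	117.15	85.1	84	5	3	155	23.7	64	141	5.9	0.13	5.96	0	0	0.14	13.92	1.06	1.7	0.59	0.386	-1.5	0.76	-1.981
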