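SYN-R-001	EXTRACELLULAR_MATRIX_ORGANIZATION	GENE0674	GENE0270	GENE0264	GENE0323	GENE0063	GENE0188	GENE0246	GENE0406	GENE0057	GENE0565	GENE0190	GENE0639	GENE0451	GENE0526	GENE0617	GENE0567	GENE0601	GENE0417	GENE0301	GENE0214	GENE0143	GENE0250	GENE0200	GENE0183	GENE0385	GENE0665	GENE0050	GENE0122	GENE0024	GENE0284	GENE0171	GENE0347
SYN-R-002	INTEGRIN_CELL_SURFACE_INTERACTIONS	GENE0443	GENE0587	GENE0525	GENE0469	GENE0337	GENE0663	GENE0132	GENE0005	GENE0268	GENE0530	GENE0592	GENE0379	GENE0544	GENE0679	GENE0045	GENE0010	GENE0267	GENE0260	GENE0640	GENE0096	GENE0155	GENE0668	GENE0304	GENE0660	GENE0107	GENE0398	GENE0442	GENE0256	GENE0073	GENE0609	GENE0156	GENE0184	GENE0190	GENE0302	GENE0641	GENE0667	GENE0429
SYN-R-003	IGF_TRANSPORT_AND_IGFBP_UPTAKE	GENE0677	GENE0377	GENE0236	GENE0571	GENE0347	GENE0136	GENE0575	GENE0306	GENE0359	GENE0062	GENE0673	GENE0054	GENE0316	GENE0280	GENE0447	GENE0168	GENE0091	GENE0255	GENE0341	GENE0226	GENE0658	GENE0448	GENE0106	GENE0003	GENE0254	GENE0294	GENE0644	GENE0301	GENE0694	GENE0385	GENE0636	GENE0581	GENE0365	GENE0412	GENE0433	GENE0345	GENE0524	GENE0639	GENE0522	GENE0734	GENE0154	GENE0478	GENE0549	GENE0390	GENE0230	GENE0622	GENE0180	GENE0463	GENE0201	GENE0205	GENE0311	GENE0305	GENE0338	GENE0038	GENE0203	GENE0183	GENE0600	GENE0449	GENE0346	GENE0256
SYN-R-004	PLATELET_DEGRANULATION	GENE0642	GENE0508	GENE0287	GENE0333	GENE0450	GENE0236	GENE0456	GENE0372	GENE0082	GENE0528	GENE0368	GENE0161	GENE0503	GENE0304	GENE0719	GENE0432	GENE0688	GENE0100	GENE0426
SYN-R-005	PI3K_AKT_SIGNALING	GENE0626	GENE0614	GENE0003	GENE0327	GENE0338	GENE0460	GENE0671	GENE0133	GENE0316	GENE0052	GENE0247	GENE0083	GENE0650	GENE0519	GENE0511	GENE0093	GENE0719	GENE0644
SYN-R-006	MAPK_FAMILY_SIGNALING	GENE0631	GENE0254	GENE0700	GENE0071	GENE0605	GENE0633	GENE0021	GENE0464	GENE0669	GENE0159	GENE0081	GENE0210	GENE0134	GENE0329	GENE0320	GENE0186	GENE0004	GENE0680	GENE0513	GENE0473	GENE0223	GENE0139	GENE0160	GENE0415	GENE0386	GENE0252	GENE0474	GENE0728	GENE0375
SYN-R-007	RTK_SIGNALING	GENE0140	GENE0229	GENE0419	GENE0174	GENE0546	GENE0497	GENE0459	GENE0380	GENE0555	GENE0611	GENE0678	GENE0200	GENE0311	GENE0359	GENE0729	GENE0397	GENE0591	GENE0015	GENE0450	GENE0002	GENE0179	GENE0127	GENE0598	GENE0438	GENE0032	GENE0063	GENE0003	GENE0482	GENE0404	GENE0388	GENE0121	GENE0020	GENE0331	GENE0230	GENE0649	GENE0437	GENE0274	GENE0088	GENE0480	GENE0458	GENE0426	GENE0022	GENE0549	GENE0172	GENE0215	GENE0722	GENE0517	GENE0471	GENE0544	GENE0255	GENE0706	GENE0157	GENE0261	GENE0624
SYN-R-008	CELL_ADHESION_MOLECULES	GENE0232	GENE0392	GENE0092	GENE0689	GENE0213	GENE0240	GENE0100	GENE0146	GENE0719	GENE0569	GENE0714	GENE0250	GENE0544	GENE0554	GENE0402	GENE0241	GENE0690	GENE0594	GENE0252	GENE0339	GENE0364	GENE0361	GENE0649	GENE0578	GENE0365	GENE0193	GENE0117	GENE0294	GENE0394	GENE0229	GENE0243	GENE0427	GENE0261	GENE0010	GENE0460	GENE0054	GENE0695	GENE0102	GENE0651	GENE0235	GENE0734	GENE0015	GENE0667
SYN-R-009	EPITHELIAL_MESENCHYMAL_TRANSITION	GENE0186	GENE0394	GENE0598	GENE0046	GENE0393	GENE0035	GENE0711	GENE0533	GENE0020	GENE0176	GENE0163	GENE0617	GENE0305	GENE0470	GENE0422
SYN-R-010	ANGIOGENESIS	GENE0591	GENE0305	GENE0348	GENE0536	GENE0457	GENE0739	GENE0303	GENE0174	GENE0389	GENE0352	GENE0218	GENE0137	GENE0232	GENE0614	GENE0708	GENE0345	GENE0616	GENE0331	GENE0369	GENE0643	GENE0127	GENE0358	GENE0214	GENE0087	GENE0584	GENE0190	GENE0143	GENE0114	GENE0173	GENE0176	GENE0397	GENE0653	GENE0655	GENE0695	GENE0152	GENE0161	GENE0025	GENE0601	GENE0548	GENE0163	GENE0302	GENE0229	GENE0376	GENE0503	GENE0179	GENE0160	GENE0594
SYN-R-011	KERATINOCYTE_DIFFERENTIATION	GENE0326	GENE0503	GENE0099	GENE0344	GENE0090	GENE0523	GENE0248	GENE0225	GENE0639	GENE0478	GENE0129	GENE0411	GENE0440	GENE0649	GENE0540	GENE0056	GENE0297	GENE0733	GENE0654	GENE0684	GENE0084	GENE0353	GENE0241	GENE0213	GENE0195	GENE0157	GENE0317	GENE0629	GENE0152	GENE0275	GENE0109	GENE0017	GENE0635	GENE0350	GENE0083	GENE0016	GENE0023	GENE0134	GENE0304	GENE0420	GENE0165	GENE0706
SYN-R-012	NEURAL_CELL_ADHESION	GENE0343	GENE0185	GENE0433	GENE0055	GENE0542	GENE0597	GENE0222	GENE0428	GENE0179	GENE0067	GENE0231	GENE0569	GENE0593	GENE0560	GENE0681	GENE0117	GENE0601	GENE0120	GENE0303	GENE0228	GENE0599	GENE0557	GENE0718	GENE0709	GENE0034	GENE0734	GENE0572	GENE0355	GENE0128	GENE0161	GENE0452	GENE0036	GENE0214	GENE0353	GENE0609	GENE0275
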