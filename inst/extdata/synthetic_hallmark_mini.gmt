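SYN_HALLMARK_PROLIFERATION	synthetic gene module over simulated cohort gene ids	G0001	G0002	G0003	G0004	G0005	G0006	G0007	G0008	G0009	G0010	G0011	G0012	G0013	G0014	G0015	G0016	G0017	G0018	G0019	G0020
SYN_HALLMARK_WNT_SIGNALING	synthetic gene module over simulated cohort gene ids	G0021	G0022	G0023	G0024	G0025	G0026	G0027	G0028	G0029	G0030	G0031	G0032	G0033	G0034	G0035	G0036	G0037	G0038
SYN_HALLMARK_DNA_REPAIR	synthetic gene module over simulated cohort gene ids	G0039	G0040	G0041	G0042	G0043	G0044	G0045	G0046	G0047	G0048	G0049	G0050	G0051	G0052	G0053	G0054	G0055
SYN_HALLMARK_HYPOXIA	synthetic gene module over simulated cohort gene ids	G0056	G0057	G0058	G0059	G0060	G0061	G0062	G0063	G0064	G0065	G0066	G0067	G0068	G0069	G0070	G0071	G0072	G0073	G0074	G0075
SYN_HALLMARK_IMMUNE_RESPONSE	synthetic gene module over simulated cohort gene ids	G0251	G0108	G0119	G0097	G0192	G0181	G0265	G0203	G0177	G0235	G0088	G0095	G0234	G0143	G0084	G0285	G0163	G0233	G0161	G0159	G0291	G0217	G0207	G0153	G0172
SYN_HALLMARK_METABOLISM	synthetic gene module over simulated cohort gene ids	G0082	G0285	G0274	G0241	G0169	G0235	G0162	G0133	G0129	G0192	G0121	G0119	G0261	G0202	G0140	G0217	G0135	G0234	G0257	G0266
SYN_EGFR_THERAPY_SIGNATURE	synthetic gene module over simulated cohort gene ids	G0166	G0231	G0207	G0160	G0071	G0123	G0285	G0268	G0201	G0104	G0243	G0040	G0103	G0068	G0271	G0294	G0095	G0188
SYN_RADIOTHERAPY_SIGNATURE	synthetic gene module over simulated cohort gene ids	G0091	G0058	G0106	G0181	G0284	G0288	G0015	G0100	G0273	G0099	G0039	G0185	G0179	G0248	G0101
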