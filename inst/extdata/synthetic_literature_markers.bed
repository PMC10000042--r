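chrS	1500	3500	SYN_MARKER_01	0	.
chrS	6500	8500	SYN_MARKER_02	0	.
chrS	11500	13500	SYN_MARKER_03	0	.
chrS	16500	18500	SYN_MARKER_04	0	.
chrS	21500	23500	SYN_MARKER_05	0	.
chrS	26500	28500	SYN_MARKER_06	0	.
chrS	31500	33500	SYN_MARKER_07	0	.
chrS	36500	38500	SYN_MARKER_08	0	.
chrS	41500	43500	SYN_MARKER_09	0	.
chrS	46500	48500	SYN_MARKER_10	0	.
chrS	51500	53500	SYN_MARKER_11	0	.
chrS	56500	58500	SYN_MARKER_12	0	.
chrS	61500	63500	SYN_MARKER_13	0	.
chrS	66500	68500	SYN_MARKER_14	0	.
chrS	71500	73500	SYN_MARKER_15	0	.
chrS	76500	78500	SYN_MARKER_16	0	.
chrS	81500	83500	SYN_MARKER_17	0	.
chrS	86500	88500	SYN_MARKER_18	0	.
chrS	91500	93500	SYN_MARKER_19	0	.
chrS	96500	98500	SYN_MARKER_20	0	.
chrS	101500	103500	SYN_MARKER_21	0	.
chrS	106500	108500	SYN_MARKER_22	0	.
chrS	111500	113500	SYN_MARKER_23	0	.
chrS	116500	118500	SYN_MARKER_24	0	.
chrS	121500	123500	SYN_MARKER_25	0	.
chrS	126500	128500	SYN_MARKER_26	0	.
chrS	131500	133500	SYN_MARKER_27	0	.
chrS	136500	138500	SYN_MARKER_28	0	.
chrS	141500	143500	SYN_MARKER_29	0	.
chrS	146500	148500	SYN_MARKER_30	0	.
chrS	151500	153500	SYN_MARKER_31	0	.
chrS	156500	158500	SYN_MARKER_32	0	.
chrS	161500	163500	SYN_MARKER_33	0	.
chrS	166500	168500	SYN_MARKER_34	0	.
chrS	171500	173500	SYN_MARKER_35	0	.
chrS	176500	178500	SYN_MARKER_36	0	.
chrS	181500	183500	SYN_MARKER_37	0	.
chrS	186500	188500	SYN_MARKER_38	0	.
chrS	191500	193500	SYN_MARKER_39	0	.
chrS	196500	198500	SYN_MARKER_40	0	.
chrS	201500	203500	SYN_MARKER_41	0	.
chrS	206500	208500	SYN_MARKER_42	0	.
chrS	211500	213500	SYN_MARKER_43	0	.
chrS	216500	218500	SYN_MARKER_44	0	.
chrS	221500	223500	SYN_MARKER_45	0	.
chrS	226500	228500	SYN_MARKER_46	0	.
chrS	231500	233500	SYN_MARKER_47	0	.
chrS	236500	238500	SYN_MARKER_48	0	.
chrS	241500	243500	SYN_MARKER_49	0	.
chrS	246500	248500	SYN_MARKER_50	0	.
chrS	251500	253500	SYN_MARKER_51	0	.
chrS	256500	258500	SYN_MARKER_52	0	.
chrS	261500	263500	SYN_MARKER_53	0	.
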