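study_id	target	n_patients	outcome_value	outcome_kind	followup_months
synthetic_ant_01	ANT	16	72	mean	37
synthetic_ant_02	ANT	13	68.9	mean	26
synthetic_ant_03	ANT	12	67.7	median	21
synthetic_ant_04	ANT	16	61.3	median	48
synthetic_ant_05	ANT	20	49.2	mean	31
synthetic_ant_06	ANT	15	76.6	mean	40
synthetic_ant_07	ANT	19	47.9	median	14
synthetic_ant_08	ANT	6	64.1	median	36
synthetic_ant_09	ANT	12	52.2	mean	41
synthetic_ant_10	ANT	21	-6.8	median	49
synthetic_ant_11	ANT	14	68.1	mean	53
synthetic_ant_12	ANT	11	50.1	mean	40
synthetic_ant_13	ANT	10	76.1	mean	32
synthetic_ant_14	ANT	17	66.7	mean	32
synthetic_ant_15	ANT	17	59.8	median	20
synthetic_ant_16	ANT	18	70.6	mean	18
synthetic_ant_17	ANT	10	72	mean	30
synthetic_ant_18	ANT	13	50.3	mean	38
synthetic_ant_19	ANT	19	73.3	median	50
synthetic_ant_20	ANT	15	75.7	median	45
synthetic_ant_21	ANT	9	69	median	49
synthetic_ant_22	ANT	17	75.3	median	33
synthetic_ant_23	ANT	10	10.7	median	12
synthetic_cmt_01	CMT	11	87.5	mean	12
synthetic_cmt_02	CMT	4	66	mean	40
synthetic_cmt_03	CMT	15	70.2	mean	26
synthetic_cmt_04	CMT	15	45.4	mean	20
synthetic_cmt_05	CMT	7	81.3	mean	29
synthetic_cmt_06	CMT	17	67.9	mean	39
synthetic_cmt_07	CMT	13	75.5	mean	34
synthetic_cmt_08	CMT	8	60.6	median	17
synthetic_hc_01	HC	12	62.2	median	41
synthetic_hc_02	HC	9	68.3	median	25
synthetic_hc_03	HC	7	63.2	mean	46
synthetic_hc_04	HC	8	62.9	median	32
synthetic_hc_05	HC	8	44.4	median	38
synthetic_hc_06	HC	7	77.2	mean	38
synthetic_hc_07	HC	6	70.2	mean	25
synthetic_hc_08	HC	8	72.8	mean	27
synthetic_hc_09	HC	11	53.9	mean	21
synthetic_hc_10	HC	8	46.6	median	42
synthetic_hc_11	HC	9	66.4	mean	13
synthetic_hc_12	HC	7	67.7	mean	50
synthetic_hc_13	HC	7	84	mean	34
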