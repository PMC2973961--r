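^DATABASE = GeoMiniSynthetic
^DATASET = GDS_SYNTHETIC_MINI
!dataset_title = synthetic miniature dataset for format tests (not real GEO data)
^SUBSET = GDS_SYNTHETIC_MINI_1
!subset_description = 0 hour
!subset_sample_id = GSM1,GSM2
!subset_type = time
^SUBSET = GDS_SYNTHETIC_MINI_2
!subset_description = 2 hour
!subset_sample_id = GSM3,GSM4
!subset_type = time
^SUBSET = GDS_SYNTHETIC_MINI_3
!subset_description = 6 hour
!subset_sample_id = GSM5,GSM6
!subset_type = time
^SUBSET = GDS_SYNTHETIC_MINI_4
!subset_description = 24 hour
!subset_sample_id = GSM7,GSM8
!subset_type = time
!dataset_table_begin
ID_REF	IDENTIFIER	GSM1	GSM2	GSM3	GSM4	GSM5	GSM6	GSM7	GSM8
ps_01	SYNGENE01	4.989	4.920	5.375	5.223	5.585	5.648	8.060	8.043
ps_02	SYNGENE02	5.091	4.883	5.384	5.178	5.809	5.813	7.917	8.072
ps_03	SYNGENE03	4.897	5.181	5.313	5.312	5.674	5.556	7.956	7.919
ps_04	SYNGENE04	4.878	4.837	5.201	5.437	5.728	5.858	8.054	8.117
ps_05	SYNGENE05	4.927	5.045	4.724	4.780	5.236	4.711	5.006	4.892
ps_06	SYNGENE06	5.025	5.110	4.729	4.733	5.070	4.967	5.159	4.862
ps_07	SYNGENE07	4.827	5.137	4.816	5.041	5.013	5.318	5.013	4.949
ps_08	SYNGENE08	5.098	4.891	4.827	5.007	5.279	4.954	5.282	5.060
ps_09	SYNGENE09	4.927	4.727	5.331	4.912	4.997	4.885	5.300	4.871
ps_10	SYNGENE10	4.741	5.280	4.969	5.080	5.136	5.113	4.751	5.297
ps_11	SYNGENE11	4.851	5.275	4.685	5.117	4.989	4.951	5.082	4.663
ps_12	SYNGENE12	5.184	5.090	5.125	5.096	5.027	5.408	4.957	4.889
ps_13	SYNGENE13	5.150	4.971	5.066	4.839	5.373	4.950	5.165	5.272
ps_14	SYNGENE14	4.498	5.026	4.920	5.061	5.230	4.400	5.185	5.246
ps_15	SYNGENE15	4.392	4.541	4.784	4.835	4.812	4.761	4.913	5.111
ps_16	SYNGENE16	5.000	4.727	4.985	5.028	4.988	5.193	5.014	4.852
ps_17	SYNGENE17	4.921	4.961	4.895	5.148	4.925	4.763	5.189	5.015
ps_18	SYNGENE18	4.651	5.014	5.078	5.277	5.042	4.830	5.082	5.101
ps_19	SYNGENE19	5.100	5.018	4.864	4.873	5.141	4.918	4.631	5.418
ps_20	SYNGENE20	5.054	5.065	4.850	5.048	5.130	4.634	5.022	5.196
!dataset_table_end
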