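fine_code	grouped_code
MI:2369	participant_group_01
MI:5273	participant_group_01
MI:9290	participant_group_01
MI:1252	participant_group_01
MI:8826	participant_group_01
MI:0356	participant_group_01
MI:7700	participant_group_02
MI:3954	participant_group_02
MI:9091	participant_group_02
MI:5403	participant_group_02
MI:0932	participant_group_02
MI:9189	participant_group_02
MI:5637	participant_group_03
MI:4002	participant_group_03
MI:9052	participant_group_03
MI:0259	participant_group_03
MI:5434	participant_group_03
MI:0481	participant_group_03
MI:7326	participant_group_04
MI:8491	participant_group_04
MI:2454	participant_group_04
MI:9028	participant_group_04
MI:9174	participant_group_04
MI:7789	participant_group_04
MI:5468	participant_group_05
MI:6341	participant_group_05
MI:9732	participant_group_05
MI:2274	participant_group_05
MI:2552	participant_group_05
MI:0727	participant_group_06
MI:0945	participant_group_06
MI:0626	participant_group_06
MI:4358	participant_group_06
MI:6534	participant_group_06
MI:1396	participant_group_07
MI:5123	participant_group_07
MI:2818	participant_group_07
MI:9207	participant_group_07
MI:0517	participant_group_07
MI:8225	participant_group_08
MI:9969	participant_group_08
MI:0103	participant_group_08
MI:5348	participant_group_08
MI:7146	participant_group_08
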