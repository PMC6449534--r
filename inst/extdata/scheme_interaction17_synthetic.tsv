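fine_code	grouped_code
MI:9545	interaction_group_01
MI:1693	interaction_group_01
MI:4172	interaction_group_01
MI:5897	interaction_group_01
MI:5611	interaction_group_01
MI:3619	interaction_group_02
MI:0016	interaction_group_02
MI:5445	interaction_group_02
MI:0988	interaction_group_02
MI:7810	interaction_group_02
MI:8274	interaction_group_03
MI:9106	interaction_group_03
MI:2344	interaction_group_03
MI:0149	interaction_group_03
MI:7140	interaction_group_03
MI:5689	interaction_group_04
MI:0100	interaction_group_04
MI:2346	interaction_group_04
MI:2450	interaction_group_04
MI:0091	interaction_group_04
MI:6925	interaction_group_05
MI:7349	interaction_group_05
MI:5174	interaction_group_05
MI:6995	interaction_group_05
MI:4816	interaction_group_05
MI:5878	interaction_group_06
MI:9501	interaction_group_06
MI:6782	interaction_group_06
MI:8619	interaction_group_06
MI:6586	interaction_group_06
MI:5232	interaction_group_07
MI:4680	interaction_group_07
MI:7453	interaction_group_07
MI:0951	interaction_group_07
MI:8102	interaction_group_07
MI:9729	interaction_group_08
MI:5261	interaction_group_08
MI:1925	interaction_group_08
MI:4407	interaction_group_08
MI:2859	interaction_group_08
MI:9770	interaction_group_09
MI:4856	interaction_group_09
MI:1889	interaction_group_09
MI:9467	interaction_group_09
MI:9998	interaction_group_09
MI:1907	interaction_group_10
MI:8895	interaction_group_10
MI:3310	interaction_group_10
MI:6670	interaction_group_10
MI:2310	interaction_group_10
MI:4395	interaction_group_11
MI:7614	interaction_group_11
MI:8946	interaction_group_11
MI:4895	interaction_group_11
MI:6050	interaction_group_11
MI:2910	interaction_group_12
MI:1248	interaction_group_12
MI:7382	interaction_group_12
MI:4390	interaction_group_12
MI:0607	interaction_group_12
MI:2831	interaction_group_13
MI:8738	interaction_group_13
MI:2474	interaction_group_13
MI:2236	interaction_group_13
MI:8446	interaction_group_13
MI:8460	interaction_group_14
MI:4736	interaction_group_14
MI:3482	interaction_group_14
MI:2089	interaction_group_14
MI:7361	interaction_group_14
MI:8856	interaction_group_15
MI:1122	interaction_group_15
MI:6681	interaction_group_15
MI:0162	interaction_group_15
MI:0636	interaction_group_15
MI:2754	interaction_group_16
MI:9823	interaction_group_16
MI:5664	interaction_group_16
MI:3995	interaction_group_16
MI:5817	interaction_group_16
MI:4892	interaction_group_17
MI:6774	interaction_group_17
MI:3109	interaction_group_17
MI:9354	interaction_group_17
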