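id	hit
cand_0001	1
cand_0002	1
cand_0003	1
cand_0004	1
cand_0005	1
cand_0006	1
cand_0007	1
cand_0008	1
cand_0009	1
cand_0010	1
cand_0011	1
cand_0012	1
cand_0013	1
cand_0014	1
cand_0015	1
cand_0016	0
cand_0017	0
cand_0018	0
cand_0019	0
cand_0020	0
cand_0021	0
cand_0022	0
cand_0023	0
cand_0024	0
cand_0025	0
cand_0026	0
cand_0027	0
cand_0028	0
cand_0029	0
cand_0030	0
cand_0031	0
cand_0032	0
cand_0033	0
cand_0034	0
cand_0035	0
cand_0036	0
cand_0037	0
cand_0038	0
cand_0039	0
cand_0040	0
cand_0041	0
cand_0042	0
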