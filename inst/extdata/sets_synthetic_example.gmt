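EXAMPLE_PATHWAY	synthetic	G00001	G00002	G00003	G00004	G00005	G00006	G00007	G00008	G00009	G00010	G00011	G00012
NULL_SET_01	synthetic	G00061	G00064	G00080	G00068	G00018	G00053	G00048	G00041	G00063	G00023	G00077
NULL_SET_02	synthetic	G00066	G00049	G00014	G00064	G00051	G00073	G00017	G00013	G00036	G00055	G00072	G00030	G00070
NULL_SET_03	synthetic	G00047	G00032	G00058	G00014	G00018	G00072
NULL_SET_04	synthetic	G00047	G00077	G00038	G00018	G00070	G00026	G00073	G00043	G00065	G00060	G00069	G00056	G00079	G00064
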