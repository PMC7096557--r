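nucleus_id	cell_class	cell_cluster	batch
n00001	A	A_c1	b1
n00002	A	A_c1	b2
n00003	A	A_c1	b2
n00004	A	A_c1	b1
n00005	A	A_c1	b2
n00006	A	A_c1	b2
n00007	A	A_c1	b1
n00008	A	A_c1	b1
n00009	A	A_c1	b2
n00010	A	A_c1	b1
n00011	A	A_c1	b2
n00012	A	A_c1	b1
n00013	A	A_c1	b2
n00014	A	A_c1	b2
n00015	A	A_c1	b1
n00016	A	A_c1	b2
n00017	A	A_c1	b1
n00018	A	A_c1	b2
n00019	A	A_c1	b2
n00020	A	A_c1	b2
n00021	A	A_c1	b2
n00022	A	A_c1	b2
n00023	A	A_c1	b2
n00024	A	A_c1	b1
n00025	A	A_c1	b2
n00026	A	A_c1	b2
n00027	A	A_c1	b2
n00028	A	A_c1	b1
n00029	A	A_c1	b2
n00030	A	A_c1	b2
n00031	B	B_c1	b1
n00032	B	B_c1	b2
n00033	B	B_c1	b2
n00034	B	B_c1	b2
n00035	B	B_c1	b2
n00036	B	B_c1	b2
n00037	B	B_c1	b1
n00038	B	B_c1	b1
n00039	B	B_c1	b2
n00040	B	B_c1	b2
n00041	B	B_c1	b2
n00042	B	B_c1	b2
n00043	B	B_c1	b1
n00044	B	B_c1	b2
n00045	B	B_c1	b1
n00046	B	B_c1	b1
n00047	B	B_c1	b2
n00048	B	B_c1	b2
n00049	B	B_c1	b2
n00050	B	B_c1	b2
n00051	B	B_c1	b2
n00052	B	B_c1	b1
n00053	B	B_c1	b2
n00054	B	B_c1	b1
n00055	C	C_c1	b2
n00056	C	C_c1	b1
n00057	C	C_c1	b2
n00058	C	C_c1	b2
n00059	C	C_c1	b1
n00060	C	C_c1	b2
n00061	C	C_c1	b1
n00062	C	C_c1	b1
n00063	C	C_c1	b1
n00064	C	C_c1	b1
n00065	C	C_c1	b2
n00066	C	C_c1	b2
n00067	C	C_c1	b2
n00068	C	C_c1	b2
n00069	C	C_c1	b1
n00070	C	C_c1	b1
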