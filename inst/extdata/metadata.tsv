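sample_id	compound_id	batch_id	is_vehicle
s00001		b01	TRUE
s00002		b01	TRUE
s00003		b02	TRUE
s00004		b02	TRUE
s00005	c0001	b02	FALSE
s00006	c0001	b01	FALSE
s00007	c0001	b02	FALSE
s00008	c0002	b01	FALSE
s00009	c0002	b01	FALSE
s00010	c0002	b02	FALSE
s00011	c0003	b01	FALSE
s00012	c0003	b02	FALSE
s00013	c0004	b02	FALSE
s00014	c0005	b01	FALSE
s00015	c0005	b02	FALSE
s00016	c0006	b02	FALSE
s00017	c0006	b02	FALSE
s00018	c0006	b02	FALSE
s00019	c0007	b02	FALSE
s00020	c0008	b01	FALSE
s00021	c0008	b01	FALSE
s00022	c0008	b01	FALSE
s00023	c0009	b02	FALSE
s00024	c0010	b01	FALSE
s00025	c0011	b01	FALSE
s00026	c0012	b01	FALSE
s00027	c0012	b02	FALSE
s00028	c0012	b02	FALSE
s00029	c0013	b02	FALSE
s00030	c0014	b01	FALSE
s00031	c0014	b02	FALSE
s00032	c0015	b02	FALSE
s00033	c0016	b01	FALSE
s00034	c0017	b01	FALSE
s00035	c0017	b01	FALSE
s00036	c0017	b02	FALSE
s00037	c0018	b01	FALSE
s00038	c0018	b02	FALSE
s00039	c0018	b02	FALSE
s00040	c0019	b02	FALSE
s00041	c0020	b01	FALSE
s00042	c0020	b02	FALSE
s00043	c0020	b02	FALSE
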