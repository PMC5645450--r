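T_SIGNAL_UP_01	referenced	c0004	c0010	c0012	c0014	c0015
T_NULL_001	referenced	c0002	c0007	c0008	c0013	c0014
T_NULL_002	predicted	c0010	c0011	c0012	c0013	c0020
T_NULL_003	referenced	c0001	c0005	c0010	c0017	c0020
T_NULL_004	predicted	c0007	c0008	c0009	c0018	c0020
T_NULL_005	referenced	c0002	c0007	c0010	c0011	c0014
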