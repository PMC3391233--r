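gene_a	gene_b	ka	ks	duplicate_type
ZmC3H14	ZmC3H46	0.044	0.143	segmental
ZmC3H13	ZmC3H47	0.063	0.168	segmental
ZmC3H16	ZmC3H57	0.04	0.201	segmental
ZmC3H20	ZmC3H55	0.205	0.244	segmental
ZmC3H6	ZmC3H67	0.066	0.24	segmental
ZmC3H37	ZmC3H60	0.134	0.131	segmental
ZmC3H7	ZmC3H66	0.044	0.175	segmental
ZmC3H29	ZmC3H36	0.014	0.169	segmental
ZmC3H12	ZmC3H51	0.059	0.172	segmental
ZmC3H39	ZmC3H53	0.061	0.178	segmental
ZmC3H4	ZmC3H28	0.025	0.23	segmental
ZmC3H2	ZmC3H61	0.031	0.205	segmental
ZmC3H18	ZmC3H56	0.095	0.067	segmental
ZmC3H23	ZmC3H64	0.067	0.359	segmental
ZmC3H30	ZmC3H35	0.053	0.156	segmental
ZmC3H13	ZmC3H14	0.262	0.818	tandem
ZmC3H46	ZmC3H47	0.292	0.965	tandem
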