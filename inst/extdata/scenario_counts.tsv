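experience	method	n_surveys	n_detections	n_fp
expert	DDO	52	959	31
expert	ISO	48	862	82
naive	DDO	32	545	213
naive	ISO	43	745	366
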