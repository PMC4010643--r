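sample	gene	consequence	detail	loh	set
3034	CDKN1A	frameshift	p.L59fs	0	discovery
745	CDKN1A	missense	p.W65R	1	discovery
R01	CDKN1A	stop-gain	synthetic	1	replication-synthetic
R02	CDKN1A	frameshift	synthetic	0	replication-synthetic
R03	CDKN1A	missense	synthetic	0	replication-synthetic
R04	CDKN1A	frameshift	synthetic	0	replication-synthetic
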