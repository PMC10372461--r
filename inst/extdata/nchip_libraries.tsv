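# N-ChIP library accounting (one row per library).
sample	cells	amplification_cycles	read_pairs	uniquely_aligned	after_dedup
A	800000	14	13129021	11299195	10763378
B	10000	14	21415343	5409960	2477749
C	1000	14	29857139	12170093	6718570
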