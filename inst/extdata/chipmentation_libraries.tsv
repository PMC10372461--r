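# ChIPmentation library accounting (one row per sequenced library).
# Counts as printed in the study's library QC table; the R1 read-pair count
# was printed with a malformed thousands group ("8,388,53") and is
# transcribed as 8388053, the value consistent with the printed 60%
# unique-non-duplicated cell.
sample	cells	amplification_cycles	read_pairs	uniquely_aligned	after_dedup
C1	1000000	17	5728173	7969894	6775525
R1	1000000	18	8388053	13469770	10007402
C3	10000	18	12537243	19157585	14417614
R3	10000	19	8665837	13838684	8409793
C5	1000	19	11436716	17920411	8664467
R5	1000	20	11109380	17854360	7214153
C7	100	22	11662120	15737202	4095477
R7	100	22	10566906	15221913	3827034
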