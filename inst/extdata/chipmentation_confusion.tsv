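# Interval-level confusion counts of merged ChIPmentation peak calls
# against the 6,186-peak N-ChIP reference (20% overlap fraction).
# reference_peaks is the positives denominator for sensitivity.
sample	cells	query_peaks	true_positives	false_positives	true_negatives	reference_peaks
N-ChIP	NA	6186	6186	0	6505	6186
C1_merged	1000000	6682	5833	849	6515	6186
C3_merged	10000	5504	4851	653	5822	6186
C5_merged	1000	2876	2425	451	3963	6186
C7_merged	100	10522	1285	9237	7094	6186
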