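metric	value
n_samples	96
total_raw_reads	736580268
total_read_length_bp	74394607068
total_demultiplexed_reads	684444768
undetermined_reads	52135500
snps_maf_gt_0.05	218621
snps_missing_lt_30pct	57874
snps_missing_lt_10pct	26301
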