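dataset	assembler	metric	value
hsa	Trinity	overall_mapping_rate	0.81
hsa	Oases	overall_mapping_rate	0.69
hsa	Trans-ABySS	overall_mapping_rate	1
hsa	SOAPdenovo-Trans	overall_mapping_rate	0.75
hsa	Bridger	overall_mapping_rate	0.66
hsa	BinPacker	overall_mapping_rate	0.24
hsa	IDBA-Tran	overall_mapping_rate	0
hsa	Shannon	overall_mapping_rate	0.58
hsa	SPAdes-sc	overall_mapping_rate	0.81
hsa	SPAdes-rna	overall_mapping_rate	0.93
hsa	Trinity	transcripts_ge_1000	0.22
hsa	Oases	transcripts_ge_1000	1
hsa	Trans-ABySS	transcripts_ge_1000	0.2
hsa	SOAPdenovo-Trans	transcripts_ge_1000	0.03
hsa	Bridger	transcripts_ge_1000	0.11
hsa	BinPacker	transcripts_ge_1000	0
hsa	IDBA-Tran	transcripts_ge_1000	0
hsa	Shannon	transcripts_ge_1000	0.05
hsa	SPAdes-sc	transcripts_ge_1000	0.05
hsa	SPAdes-rna	transcripts_ge_1000	0.15
hsa	Trinity	misassemblies	0.99
hsa	Oases	misassemblies	0
hsa	Trans-ABySS	misassemblies	0.99
hsa	SOAPdenovo-Trans	misassemblies	1
hsa	Bridger	misassemblies	0.97
hsa	BinPacker	misassemblies	0.98
hsa	IDBA-Tran	misassemblies	1
hsa	Shannon	misassemblies	0.99
hsa	SPAdes-sc	misassemblies	0.99
hsa	SPAdes-rna	misassemblies	0.98
hsa	Trinity	mismatches_per_transcript	0.74
hsa	Oases	mismatches_per_transcript	0.77
hsa	Trans-ABySS	mismatches_per_transcript	0.93
hsa	SOAPdenovo-Trans	mismatches_per_transcript	1
hsa	Bridger	mismatches_per_transcript	0.73
hsa	BinPacker	mismatches_per_transcript	0
hsa	IDBA-Tran	mismatches_per_transcript	0.91
hsa	Shannon	mismatches_per_transcript	0.77
hsa	SPAdes-sc	mismatches_per_transcript	0.88
hsa	SPAdes-rna	mismatches_per_transcript	0.78
hsa	Trinity	avg_alignment_length	0.27
hsa	Oases	avg_alignment_length	0.06
hsa	Trans-ABySS	avg_alignment_length	0.01
hsa	SOAPdenovo-Trans	avg_alignment_length	0
hsa	Bridger	avg_alignment_length	0.21
hsa	BinPacker	avg_alignment_length	1
hsa	IDBA-Tran	avg_alignment_length	0.13
hsa	Shannon	avg_alignment_length	0.23
hsa	SPAdes-sc	avg_alignment_length	0.09
hsa	SPAdes-rna	avg_alignment_length	0.09
hsa	Trinity	isoforms_95pct	0.99
hsa	Oases	isoforms_95pct	0.1
hsa	Trans-ABySS	isoforms_95pct	1
hsa	SOAPdenovo-Trans	isoforms_95pct	0.31
hsa	Bridger	isoforms_95pct	0.28
hsa	BinPacker	isoforms_95pct	0.39
hsa	IDBA-Tran	isoforms_95pct	0.07
hsa	Shannon	isoforms_95pct	0
hsa	SPAdes-sc	isoforms_95pct	0.23
hsa	SPAdes-rna	isoforms_95pct	0.46
hsa	Trinity	duplication_ratio	0
hsa	Oases	duplication_ratio	0.03
hsa	Trans-ABySS	duplication_ratio	0.47
hsa	SOAPdenovo-Trans	duplication_ratio	0.87
hsa	Bridger	duplication_ratio	0.5
hsa	BinPacker	duplication_ratio	0.01
hsa	IDBA-Tran	duplication_ratio	1
hsa	Shannon	duplication_ratio	0.63
hsa	SPAdes-sc	duplication_ratio	1
hsa	SPAdes-rna	duplication_ratio	0.87
hsa	Trinity	ex90n50	0
hsa	Oases	ex90n50	0.17
hsa	Trans-ABySS	ex90n50	0.06
hsa	SOAPdenovo-Trans	ex90n50	0.19
hsa	Bridger	ex90n50	0.51
hsa	BinPacker	ex90n50	1
hsa	IDBA-Tran	ex90n50	0.19
hsa	Shannon	ex90n50	0.49
hsa	SPAdes-sc	ex90n50	0.42
hsa	SPAdes-rna	ex90n50	0.22
hsa	Trinity	full_length_transcripts	0.97
hsa	Oases	full_length_transcripts	0.83
hsa	Trans-ABySS	full_length_transcripts	1
hsa	SOAPdenovo-Trans	full_length_transcripts	0.64
hsa	Bridger	full_length_transcripts	0.89
hsa	BinPacker	full_length_transcripts	0.26
hsa	IDBA-Tran	full_length_transcripts	0
hsa	Shannon	full_length_transcripts	0.63
hsa	SPAdes-sc	full_length_transcripts	0.46
hsa	SPAdes-rna	full_length_transcripts	0.69
hsa	Trinity	reference_coverage	0.87
hsa	Oases	reference_coverage	0.33
hsa	Trans-ABySS	reference_coverage	1
hsa	SOAPdenovo-Trans	reference_coverage	0.34
hsa	Bridger	reference_coverage	0.31
hsa	BinPacker	reference_coverage	0.27
hsa	IDBA-Tran	reference_coverage	0.31
hsa	Shannon	reference_coverage	0
hsa	SPAdes-sc	reference_coverage	0.3
hsa	SPAdes-rna	reference_coverage	0.42
hsa	Trinity	mean_orf_percentage	0.64
hsa	Oases	mean_orf_percentage	0
hsa	Trans-ABySS	mean_orf_percentage	0.72
hsa	SOAPdenovo-Trans	mean_orf_percentage	0.44
hsa	Bridger	mean_orf_percentage	0.22
hsa	BinPacker	mean_orf_percentage	0.04
hsa	IDBA-Tran	mean_orf_percentage	0.76
hsa	Shannon	mean_orf_percentage	1
hsa	SPAdes-sc	mean_orf_percentage	0.3
hsa	SPAdes-rna	mean_orf_percentage	0.31
hsa	Trinity	transrate_optimal_score	0.3
hsa	Oases	transrate_optimal_score	0
hsa	Trans-ABySS	transrate_optimal_score	0.23
hsa	SOAPdenovo-Trans	transrate_optimal_score	0.66
hsa	Bridger	transrate_optimal_score	0.32
hsa	BinPacker	transrate_optimal_score	0.14
hsa	IDBA-Tran	transrate_optimal_score	0.61
hsa	Shannon	transrate_optimal_score	0.13
hsa	SPAdes-sc	transrate_optimal_score	1
hsa	SPAdes-rna	transrate_optimal_score	0.57
hsa	Trinity	pct_bases_uncovered	0.38
hsa	Oases	pct_bases_uncovered	0
hsa	Trans-ABySS	pct_bases_uncovered	0.33
hsa	SOAPdenovo-Trans	pct_bases_uncovered	0.67
hsa	Bridger	pct_bases_uncovered	0.57
hsa	BinPacker	pct_bases_uncovered	0.11
hsa	IDBA-Tran	pct_bases_uncovered	1
hsa	Shannon	pct_bases_uncovered	0.48
hsa	SPAdes-sc	pct_bases_uncovered	0.99
hsa	SPAdes-rna	pct_bases_uncovered	0.79
hsa	Trinity	ambiguous_bases	0.72
hsa	Oases	ambiguous_bases	0
hsa	Trans-ABySS	ambiguous_bases	0.53
hsa	SOAPdenovo-Trans	ambiguous_bases	0.78
hsa	Bridger	ambiguous_bases	0.83
hsa	BinPacker	ambiguous_bases	1
hsa	IDBA-Tran	ambiguous_bases	0.91
hsa	Shannon	ambiguous_bases	0.94
hsa	SPAdes-sc	ambiguous_bases	0.86
hsa	SPAdes-rna	ambiguous_bases	0.71
hsa	Trinity	nucleotide_f1	0.59
hsa	Oases	nucleotide_f1	0.08
hsa	Trans-ABySS	nucleotide_f1	0.77
hsa	SOAPdenovo-Trans	nucleotide_f1	0.89
hsa	Bridger	nucleotide_f1	0.71
hsa	BinPacker	nucleotide_f1	0
hsa	IDBA-Tran	nucleotide_f1	0.86
hsa	Shannon	nucleotide_f1	0.42
hsa	SPAdes-sc	nucleotide_f1	0.97
hsa	SPAdes-rna	nucleotide_f1	1
hsa	Trinity	contig_f1	0.08
hsa	Oases	contig_f1	0.09
hsa	Trans-ABySS	contig_f1	0.99
hsa	SOAPdenovo-Trans	contig_f1	1
hsa	Bridger	contig_f1	0.05
hsa	BinPacker	contig_f1	0
hsa	IDBA-Tran	contig_f1	0.08
hsa	Shannon	contig_f1	0.11
hsa	SPAdes-sc	contig_f1	0.07
hsa	SPAdes-rna	contig_f1	0.06
hsa	Trinity	kc_score	0.87
hsa	Oases	kc_score	0
hsa	Trans-ABySS	kc_score	1
hsa	SOAPdenovo-Trans	kc_score	0.42
hsa	Bridger	kc_score	0.51
hsa	BinPacker	kc_score	0.4
hsa	IDBA-Tran	kc_score	0.14
hsa	Shannon	kc_score	0.58
hsa	SPAdes-sc	kc_score	0.47
hsa	SPAdes-rna	kc_score	0.6
hsa	Trinity	rsem_eval	0.98
hsa	Oases	rsem_eval	0.45
hsa	Trans-ABySS	rsem_eval	1
hsa	SOAPdenovo-Trans	rsem_eval	0.72
hsa	Bridger	rsem_eval	0.85
hsa	BinPacker	rsem_eval	0.62
hsa	IDBA-Tran	rsem_eval	0
hsa	Shannon	rsem_eval	0.73
hsa	SPAdes-sc	rsem_eval	0.42
hsa	SPAdes-rna	rsem_eval	0.91
hsa	Trinity	complete_buscos	0.96
hsa	Oases	complete_buscos	0.79
hsa	Trans-ABySS	complete_buscos	1
hsa	SOAPdenovo-Trans	complete_buscos	0.39
hsa	Bridger	complete_buscos	0.92
hsa	BinPacker	complete_buscos	0.13
hsa	IDBA-Tran	complete_buscos	0
hsa	Shannon	complete_buscos	0.7
hsa	SPAdes-sc	complete_buscos	0.39
hsa	SPAdes-rna	complete_buscos	0.58
hsa	Trinity	missing_buscos	0.99
hsa	Oases	missing_buscos	0.93
hsa	Trans-ABySS	missing_buscos	1
hsa	SOAPdenovo-Trans	missing_buscos	0.83
hsa	Bridger	missing_buscos	0.98
hsa	BinPacker	missing_buscos	0
hsa	IDBA-Tran	missing_buscos	0.63
hsa	Shannon	missing_buscos	0.84
hsa	SPAdes-sc	missing_buscos	0.78
hsa	SPAdes-rna	missing_buscos	0.92
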