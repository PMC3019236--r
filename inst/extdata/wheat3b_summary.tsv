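# Whole-chromosome mapping summary for wheat chromosome 3B (example dataset).
# Counts of probes/loci from the pooled-hybridisation screen and its
# cross-species mapping, plus the array and genome constants used in the
# expected-probe calculation.
quantity	value
probes_on_map	738
loci_on_map	757
loci_in_bins	519
barley_mapped	308
barley_3h	209
barley_other	99
rice_mapped	659
rice_1	389
rice_other	270
binned_barley_3h	153
binned_barley_other	57
collinear_3h	102
binned_rice_1	285
collinear_rice_1	185
array_probes	15208
chr3h_genome_fraction_pct	14.8
mtp_coverage_fraction	0.82
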