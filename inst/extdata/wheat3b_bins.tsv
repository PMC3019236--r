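# Deletion-bin mapping summary for wheat chromosome 3B (example dataset).
# contig_length_mb: cumulative length of physical-map contigs assigned to the bin.
# n_loci: gene loci assigned to the bin by pooled BAC hybridisation.
# barley_3h / barley_other: loci mapped on barley chromosome 3H / other barley chromosomes.
# collinear_3h: loci collinear between the bin and its barley 3H synteny block.
# rice_1 / rice_other / collinear_rice_1: same against rice chromosome 1.
bin	contig_length_mb	n_loci	barley_3h	barley_other	collinear_3h	rice_1	rice_other	collinear_rice_1
3BS8-0.78-1.00	44.2	37	10	9	7	15	14	10
3BS9-0.57-0.78	43.2	43	12	4	9	22	16	16
3BS1-0.33-0.57	94.3	86	14	11	8	40	33	20
C-3BS1-0.33	58.3	34	9	1	4	23	7	16
C-3BL2-0.22	45.7	36	15	3	8	27	6	18
3BL2-0.22-0.50	74.9	78	25	10	21	47	26	38
3BL10-0.50-0.63	40.1	40	13	5	8	18	17	8
3BL7-0.63-1.00	155.5	165	55	14	37	93	57	59
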