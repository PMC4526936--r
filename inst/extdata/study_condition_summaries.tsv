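# Per-condition comprehension score summaries (0-10 scale) from a published
# between-subjects evaluation of the seven report designs, with the
# per-condition sample sizes of that study. Provenance note: the study's
# abstract reports 730 analyzed participants, its results section 731; the
# per-condition ns below sum to 730.
condition	n	mean	sd
table	105	5.65	1.83
bar	103	6.21	1.56
bubble	115	6.30	1.44
treemap	102	5.74	1.72
heatmap	104	6.25	1.40
zoom_treemap	96	4.63	2.16
zoom_partition	105	5.08	1.90
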