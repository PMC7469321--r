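# tss_coordinate: 11907840
# region: Chr1:11908117-11908380 (GRCh37, minus strand)
Chr1	11908353	11908353	CpG1	-
Chr1	11908348	11908348	CpG2	-
Chr1	11908299	11908299	CpG3	-
Chr1	11908200	11908200	CpG4	-
Chr1	11908182	11908182	CpG5	-
Chr1	11908178	11908178	CpG6	-
Chr1	11908168	11908168	CpG7	-
Chr1	11908165	11908165	CpG8	-
Chr1	11908142	11908142	CpG9	-
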