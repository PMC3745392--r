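# Distribution of Baltic grey seal mtDNA control-region haplotypes across
# the three breeding sites, from the re-edited chromatogram dataset.
# BB = Bay of Bothnia, EST = Estonia, STA = Stockholm Archipelago.
# aux = count in an auxiliary (unpublished) grey seal dataset.
# old_id = originally deposited repository haplotype id(s); "New" marks
# haplotypes absent from the repository. Haplotypes HT36-HT38 were seen
# only in the auxiliary dataset (zero Baltic counts).
haplotype	BB	EST	STA	aux	old_id
HT1	4	5	3	14	5,28
HT2	4	4	3	2	19,21,29
HT3	3	3	3	3	New
HT4	1	3	5	5	23
HT5	3	3	0	3	27
HT6	2	1	2	16	38
HT7	3	1	0	3	New
HT8	1	1	1	0	New
HT9	2	1	0	0	14
HT10	1	1	1	0	New
HT11	1	1	1	2	New
HT12	2	1	0	0	11,17
HT13	1	2	0	2	16,25
HT14	0	0	2	1	New
HT15	0	2	0	0	New
HT16	1	1	0	0	24
HT17	0	0	2	2	New
HT18	1	1	0	4	7,9
HT19	1	1	0	0	18
HT20	0	0	2	0	New
HT21	1	0	0	0	12
HT22	1	0	0	0	15
HT23	1	0	0	0	20
HT24	1	0	0	1	New
HT25	1	0	0	1	New
HT26	1	0	0	1	New
HT27	1	0	0	0	New
HT28	1	0	0	1	New
HT29	0	1	0	0	22
HT30	0	1	0	0	New
HT31	0	1	0	0	New
HT32	0	1	0	0	New
HT33	0	0	1	0	New
HT34	0	0	1	1	New
HT35	0	0	1	0	3
HT36	0	0	0	3	31,32,37,40
HT37	0	0	0	20	34
HT38	0	0	0	4	35
Total	39	36	28	89	
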