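# SYNTHETIC stand-in for the uncorrected ("erroneous") dataset distribution:
# 108 individuals (BB 40, EST 40, STA 28) spread over the 40 deposited
# repository haplotypes. The published distribution behind the real
# uncorrected dataset is not reproduced here; only its shape (row count and
# column totals) is emulated. Row i refers to repository haplotype i by
# ordinal position.
haplotype	BB	EST	STA
GB1	1	0	0
GB2	0	0	3
GB3	0	1	1
GB4	0	0	2
GB5	0	1	0
GB6	1	1	0
GB7	1	0	0
GB8	0	7	0
GB9	1	0	0
GB10	0	2	2
GB11	1	2	0
GB12	3	1	2
GB13	3	3	3
GB14	1	4	1
GB15	0	1	0
GB16	0	1	0
GB17	1	0	0
GB18	0	1	0
GB19	0	1	0
GB20	0	0	1
GB21	2	3	0
GB22	1	0	0
GB23	1	0	0
GB24	1	1	0
GB25	1	0	0
GB26	3	1	0
GB27	0	1	1
GB28	0	1	3
GB29	2	0	0
GB30	4	2	3
GB31	1	0	0
GB32	0	0	2
GB33	1	0	0
GB34	0	2	1
GB35	0	0	1
GB36	4	1	2
GB37	1	0	0
GB38	1	0	0
GB39	3	2	0
GB40	1	0	0
Total	40	40	28
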