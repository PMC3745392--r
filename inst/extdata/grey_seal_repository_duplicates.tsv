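# Groups of repository entries that carry identical sequences although
# deposited under different haplotype ids. members lists the repository
# haplotype ids; 15 entries collapse into 6 groups (9 redundant entries),
# so the 40 deposited entries represent 31 distinct haplotypes.
group	members
1	31,32,37,40
2	19,21,29
3	5,28
4	16,25
5	11,17
6	7,9
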