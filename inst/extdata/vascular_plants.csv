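# Vascular plant species frequency counts, southern Appalachians survey
# 188 species, 1008 individuals in total
# Counts at multiplicities k >= 15 are aggregated into the final "15+"
# row: 15 species holding the remaining 417 individuals.
k,f_k
1,61
2,35
3,18
4,12
5,15
6,4
7,8
8,4
9,5
10,5
11,1
12,2
13,1
14,2
15+,15
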