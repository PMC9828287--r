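# Butterfly species frequency counts, Malayan survey
# 620 species, 9031 individuals in total
# Counts at multiplicities k >= 15 are aggregated into the final "15+"
# row: 191 species holding the remaining 7092 individuals.
k,f_k
1,118
2,74
3,44
4,24
5,29
6,22
7,20
8,19
9,20
10,15
11,12
12,14
13,6
14,12
15+,191
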