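# Ground-dwelling invertebrate species frequency counts, northwest Tasmania
# 2050 individuals in total. The published summary reports 84 species while
# this frequency row sums to 85; the row is shipped verbatim and the
# discrepancy left as-is.
# Counts at multiplicities k >= 15 are aggregated into the final "15+"
# row: 24 species holding the remaining 1738 individuals.
k,f_k
1,15
2,8
3,5
4,3
5,5
6,5
7,3
8,3
9,4
10,2
11,3
12,1
13,3
14,1
15+,24
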