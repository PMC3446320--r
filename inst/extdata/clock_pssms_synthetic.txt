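# Synthetic consensus-derived stand-in PSSMs for the clock elements
# (columns: A C G T; one row per motif position; counts are renormalized
# with a pseudocount on read). Replace with curated matrices for real work.
>Ebox
1 17 1 1
17 1 1 1
1 17 1 1
1 1 17 1
1 1 1 17
1 1 17 1
>EpBox
1 17 1 1
17 1 1 1
1 17 1 1
1 1 17 1
1 1 1 17
1 1 1 17
>Dbox
1 1 1 17
1 1 1 17
17 1 1 1
1 1 1 17
1 1 17 1
1 9 1 9
17 1 1 1
17 1 1 1
>RRE
9 1 1 9
17 1 1 1
9 1 1 9
5 5 5 5
1 1 1 17
9 1 9 1
1 1 17 1
1 1 17 1
1 1 1 17
1 17 1 1
17 1 1 1
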