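# Example CRE-associated IUPAC motifs (Polycomb response element style
# cores: GA-repeat / GAGA factor, PHO-like, GT-repeat).
GAF	GAGAG
GA_repeat	GAGAGAGA
PHO	GCCAT
PHO_extended	GCCATHWY
GT_repeat	GTGTGTGT
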