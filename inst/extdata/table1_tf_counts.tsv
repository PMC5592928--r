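species	ploidy	transcripts	genes	families	group
Oryza sativa subsp. indica	2x	1891	1891	56	rice
Oryza sativa subsp. japonica (MSU)	2x	2408	1859	56	rice
Hordeum vulgare	2x	2621	1198	56	diploid_triticeae
Aegilops tauschii	2x	1439	1439	55	diploid_triticeae
Triticum urartu	2x	888	888	50	diploid_triticeae
Triticum aestivum (ESTs Unigene #63)	6x	1940	1940	56	polyploid_est
Triticum aestivum (TGAC high-confidence)	6x	8609	5776	56	polyploid_tgac
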