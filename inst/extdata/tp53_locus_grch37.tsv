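chrom	start	end	gene
17	7571719	7590868	TP53
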