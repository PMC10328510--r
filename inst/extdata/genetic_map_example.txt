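Chromosome Position(bp) Rate(cM/Mb) Map(cM)
chr1 0 1.0 0.0
chr1 500000 2.0 0.5
chr1 900000 0.0 1.3
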