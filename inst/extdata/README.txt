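synthetic_RNASEH1_like.fa / .gtf

A SYNTHETIC stand-in transcript (generated by
uorfkit::make_genome_and_annotation, seed 42: 100 nt 5' UTR, 807 nt CDS
including stop, 500 nt 3' UTR) engineered to share the uORF architecture of
the RNASEH1 mRNA: a single uORF that overlaps the pORF start codon and
encodes a 9-amino-acid peptide. It is NOT the RNASEH1 sequence; it exists so
the worked example and its checks run fully offline.
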