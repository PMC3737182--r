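# Example data

`g6pd_synthetic_haplotypes.tsv` / `g6pd_synthetic_mask.tsv` — a synthetic
10-haplotype, 25-SNP input reconstructed from the published coded sample
configuration of the G6PD 202-A selected haplotypes
({(11,7): 5, (4,7): 1, (12,7): 1, (17,7): 3}); markers are spaced uniformly
over the 440-kb region and the selected site sits at column 18
(position 311667). The allele values inside each retained block follow an
arbitrary ancestral haplotype pattern; alleles outside the blocks are
arbitrary. Only the coded configuration is real data; everything else is
synthetic scaffolding for the readers and the worked example.
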