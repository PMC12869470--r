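# Canonical TSS positions, GRCh38 (Ensembl), 1-based
gene	chrom	tss	strand
NCAM1	chr11	112961247	+
IFNG	chr12	68159740	-
KIR2DL1	chr19	54772663	+
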