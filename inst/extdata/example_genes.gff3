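##gff-version 3
##source-version rtracklayer 1.62.0
##date 2026-09-21
gene001	poolrens	CDS	1	60	.	+	0	ID=cds-gene001-1;Parent=gene001
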