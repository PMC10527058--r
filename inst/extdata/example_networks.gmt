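developmental_biology	Developmental biology	CLTB	GRN
disease	Disease	APP	HEXA
extracellular_matrix	Extracellular matrix organisation	APP
gene_expression	Gene expression (transcription)	GRN
haemostasis	Haemostasis	APP	GRN
immune_system	Immune system	APP	CST3	GRN
metabolism	Metabolism	CAD	COPE	HEXA	QARS	SIAE
metabolism_of_protein	Metabolism of protein	APP	COPE	CST3	QARS	WARS
metabolism_of_rna	Metabolism of RNA	QARS
muscle_contraction	Muscle contraction	CAD	GRN	MYH8
programmed_cell_death	Programmed cell death	CAD
protein_localisation	Protein localisation	APP
signal_transduction	Signal transduction	APP
vesicle_transport	Vesicle-mediated transport	APP	CLTB	COPE	GOLIM4	SCARB2
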