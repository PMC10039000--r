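cancer_type	histology	origin	pct_tp53_mutant	pct_gof	cluster
ACC	non_adenocarcinoma	mesoderm	15.9	9.1	A1
BLCA	non_adenocarcinoma	endoderm	47.0	41.3	A1
BRCA	adenocarcinoma	ectoderm	31.0	34.2	A1
ESCA	adenocarcinoma	endoderm	86.1	46.6	A1
GBM	non_adenocarcinoma	ectoderm	31.4	53.5	A1
KICH	non_adenocarcinoma	mesoderm	24.6	21.4	A1
LGG	non_adenocarcinoma	ectoderm	46.4	61.1	A1
LIHC	non_adenocarcinoma	endoderm	27.5	42.2	A1
LUAD	adenocarcinoma	endoderm	44.7	23.2	A1
LUSC	non_adenocarcinoma	endoderm	83.0	32.6	A1
MESO	non_adenocarcinoma	mesoderm	15.1	23.1	A1
OV	adenocarcinoma	mesoderm	94.1	35.9	A1
PAAD	non_adenocarcinoma	endoderm	49.6	42.9	A1
PRAD	adenocarcinoma	mesoderm	9.5	32.6	A1
SARC	non_adenocarcinoma	mesoderm	32.5	32.8	A1
STAD	adenocarcinoma	endoderm	43.7	38.3	A1
UCEC	adenocarcinoma	mesoderm	35.1	49.7	A1
CESC	non_adenocarcinoma	mesoderm	7.7	19.0	A2
COAD	adenocarcinoma	endoderm	52.0	48.5	A2
HNSC	non_adenocarcinoma	ectoderm	66.3	11.2	A2
READ	adenocarcinoma	endoderm	71.4	54.4	A2
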