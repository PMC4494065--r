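label	gene_id	position	ref	alt	bold	nonsynonymous_note
QCR07-116	QCR7	116	G	A	FALSE	TRUE
ATP5O-537	ATP5O	537	A	G	TRUE	FALSE
MTCO2-624	MTCO2	624	C	T	FALSE	FALSE
MTCO3-324	MTCO3	324	C	A	FALSE	FALSE
MTCYTB-945	MTCYTB	945	A	T	FALSE	FALSE
MTCO1-1056	MTCO1	1056	A	G	TRUE	FALSE
MTCO1-1281	MTCO1	1281	A	G	TRUE	FALSE
MTCO2-594	MTCO2	594	A	G	TRUE	FALSE
MTCO3-459	MTCO3	459	A	G	TRUE	FALSE
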