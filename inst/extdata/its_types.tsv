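label	species	gc_percent	b122	m122	b135	m135	b226	m226	b500	m500	supposed_parents	n_specimens	accession
P0	C. pilosula	60.61	C	NA	G	NA	C	NA	G	NA	NA	NA	EF190460
P1	C. pilosula	60.31	Y	T	G	NA	Y	C	G	NA	P0 x S0	33	NA
P2	C. pilosula	60.46	C	NA	G	NA	Y	C	G	NA	NA	1	NA
P3	C. pilosula	60.31	Y	T	G	NA	Y	T	G	NA	P0 x S0	1	NA
P4	C. pilosula	60.31	Y	C	G	NA	Y	C	G	NA	P0 x S0	2	NA
P5	C. pilosula	60.46	Y	C	G	NA	C	NA	G	NA	P0 x PM0	2	NA
PM0	C. pilosula var. modesta	60.46	T	NA	G	NA	C	NA	G	NA	NA	NA	EF190461
PM1	C. pilosula var. modesta	60.31	Y	T	G	NA	Y	C	G	NA	P0 x S0	4	NA
PM2	C. pilosula var. modesta	60.31	T	NA	G	NA	Y	C	G	NA	S0 x PM0	1	NA
PM3	C. pilosula var. modesta	60.46	Y	T	G	NA	C	NA	G	NA	P0 x PM0	1	NA
T0	C. tangshen	60.31	T	NA	G	NA	C	NA	A	NA	NA	NA	EF190462
T1	C. tangshen	60.15	T	NA	R	NA	C	NA	R	NA	NA	1	NA
S0	Codonopsis sp.	60.31	T	NA	G	NA	T	NA	G	NA	NA	NA	AB769272
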