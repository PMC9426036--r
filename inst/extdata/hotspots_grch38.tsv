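# wgdclock bundled hotspot table, v1 (GRCh38)
# Coordinates curated from the canonical transcripts (IDH1
# ENST00000345146, IDH2 ENST00000330062; both on the minus strand) and
# the TERT promoter region.  Users supplying their own table are
# responsible for matching their genome build; the build is recorded
# per row.
gene	label	chrom	pos	ref	alts	build
IDH1	R132H	2	208248388	C	T	GRCh38
IDH1	R132L	2	208248388	C	A	GRCh38
IDH1	R132C	2	208248389	G	A	GRCh38
IDH1	R132G	2	208248389	G	C	GRCh38
IDH1	R132S	2	208248389	G	T	GRCh38
IDH2	R172K	15	90088606	C	T	GRCh38
IDH2	R172M	15	90088606	C	A	GRCh38
IDH2	R172S	15	90088605	C	A	GRCh38
IDH2	R172G	15	90088607	T	C	GRCh38
IDH2	R172W	15	90088607	T	A	GRCh38
TERT	C228T	5	1295113	G	A	GRCh38
TERT	C250T	5	1295135	G	A	GRCh38
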