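chrom	pos	ref	alt	gene	rsid	gnomad_popmax_af	topmed_af	nfe_af	consequence	sift_label	polyphen_label	phastcons7	hgvsc	hgvsp	family_id
chr1	100100	G	A	DENND2C	rs189506550	<0.001	<0.001	<0.001	missense	tolerated	probably_damaging	1	c.842G>A	p.Arg281Gln	1
chr1	100200	T	C	DENND2C	rs61753528	0.005	0.003	0.005	missense	deleterious	probably_damaging	1	c.2497T>C	p.Tyr833His	10
chr2	200100	A	T	DNAH7	rs201273652	0.005	<0.001	<0.001	missense	deleterious	probably_damaging	1	c.3233A>T	p.Glu1078Val	8
chr2	200200	CT	C	DNAH7	rs115474479	<0.001	<0.001	<0.001	stop_gained	.	.	0.981	c.6949C>T	p.Arg2317Ter	2
chr2	300100	G	A	NBEAL1	rs199629983	0.004	0.001	0.001	missense	deleterious	possibly_damaging	0.918	c.5252G>A	p.Arg1751His	9
chr2	300200	T	G	NBEAL1	rs180771101	0.003	0.002	0.003	missense	deleterious	probably_damaging	1	c.987T>G	p.Phe329Leu	2
chr2	400100	A	G	NEB	rs201548700	<0.001	<0.001	<0.001	missense	deleterious	probably_damaging	0.999	c.22187A>G	p.Lys7396Arg	4
chr2	400200	A	G	NEB	rs114089598	0.005	0.003	0.004	missense	tolerated	probably_damaging	0.999	c.4649A>G	p.Lys1550Arg	8
chr2	400300	T	C	NEB	rs764064217	<0.001	<0.001	<0.001	missense	tolerated	possibly_damaging	0.998	c.6011T>C	p.Val2004Ala	9
chr1	500100	A	G	PRRC2C	rs148813704	0.004	0.003	0.004	missense	deleterious	benign	0.986	c.5980A>G	p.Asn1994Asp	3
chr1	500200	A	G	PRRC2C	rs138220849	0.002	0.001	<0.001	missense	deleterious	benign	1	c.2191A>G	p.Met731Val	2
chr19	600100	T	G	SHC2	rs201010410	<0.001	<0.001	<0.001	missense	deleterious	probably_damaging	0.991	c.1595T>G	p.Leu532Arg	3
chr19	600200	G	T	SHC2	rs768095487	<0.001	<0.001	<0.001	missense	deleterious	probably_damaging	0.274	c.1510G>T	p.Asp504Tyr	4
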