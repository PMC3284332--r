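progeny_id	co_class	distal_flank_pos	distal_parent	proximal_flank_pos	proximal_parent	span	band	location	gene
2d	SCO	2413159	P1	2413912	P2	753	3A4	intron	trol
3a	SCO	4860933	P1	4861309	P2	376	4E1	intergenic	NA
1e	DCO	5441397	P2	5441591	P1	194	5A4	intron	Vsx2
1a	SCO	6601365	P1	6601675	P2	310	6C8	intron	CG14441
1b	SCO	8000862	P1	8001116	P2	254	7D6	intron	Gclc
2c	SCO	8834132	P2	8834399	P1	267	8C1	intron	rdgA
3b	SCO	8862810	P2	8863096	P1	286	8C1	intron	rdgA
2e	SCO	10437477	P1	10455495	P2	18018	9D3	intron_exon	spri
4a	DCO	11968504	P2	11969790	P1	1286	11A3	intergenic	NA
2a	DCO	11992791	P1	11994201	P2	1410	11A3	intergenic	NA
1c	SCO	12813592	P1	12814988	P2	1396	11D3	intergenic	NA
1d	SCO	15696462	P2	15697193	P1	731	13F1	intron_exon_intergenic	PGRP-LE
1e	DCO	16511826	P1	16514097	P2	2271	14F2	intron	CG9782
4a	DCO	19291635	P1	19293197	P2	1562	18C3	intron	kek5
2a	DCO	19451465	P2	19453294	P1	1829	18D1	intergenic	NA
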